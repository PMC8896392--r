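#' Class-membership weights for downstream proteins
#'
#' Crosstalk means the same protein sits downstream of several effector
#' classes; counting it fully in each class would over-represent shared
#' proteins. Each downstream protein is therefore weighted by 1/k in each of
#' the k classes it belongs to, so its weights sum to exactly 1.
#'
#' @param network A `layered_network`.
#' @return A tibble with columns `protein`, `class_id`, `weight`.
#' @examples
#' # A protein downstream of classes 1 and 12 carries weight 0.5 in each.
#' @export
class_weights <- function(network) {
  stopifnot(inherits(network, "layered_network"))
  sets <- network$protein_classes
  if (nrow(sets) == 0) {
    return(tibble(protein = character(), class_id = integer(),
                  weight = double()))
  }
  class_list <- split_int_set(sets$classes)
  tibble(
    protein = rep(sets$protein, lengths(class_list)),
    class_id = unlist(class_list),
    weight = rep(1 / lengths(class_list), lengths(class_list))
  ) %>%
    arrange(.data$protein, .data$class_id)
}

# Attach the annotation category to a weight table; proteins without an
# annotation row are dropped with a warning (they cannot be profiled).
join_category <- function(weights, annotations, vocabulary) {
  require_columns(annotations, c("symbol", vocabulary), "annotation table")
  joined <- left_join(weights,
                      annotations[, c("symbol", vocabulary)],
                      by = c(protein = "symbol"))
  missing <- is.na(joined[[vocabulary]])
  if (any(missing)) {
    warn(sprintf("%d weighted protein(s) lack a '%s' annotation and were dropped",
                 n_distinct(joined$protein[missing]), vocabulary))
    joined <- joined[!missing, , drop = FALSE]
  }
  rename(joined, category = dplyr::all_of(vocabulary))
}

#' Weighted functional profile per effector class
#'
#' For each class, sums the class weights of its downstream proteins per
#' annotation category and normalizes by the class-specific weight sum,
#' yielding percentages that sum to 100 within each class.
#'
#' @param weights Result of [class_weights()].
#' @param annotations Annotation table covering the weighted proteins.
#' @param vocabulary Name of the annotation column to profile on
#'   (default `"process15"`).
#' @return Tibble with `class_id`, `category`, `weight_sum`, `percent`.
#' @export
weighted_profile <- function(weights, annotations, vocabulary = "process15") {
  joined <- join_category(weights, annotations, vocabulary)
  joined %>%
    group_by(class_id = .data$class_id, category = .data$category) %>%
    summarise(weight_sum = sum(.data$weight), .groups = "drop_last") %>%
    mutate(percent = 100 * .data$weight_sum / sum(.data$weight_sum)) %>%
    ungroup() %>%
    arrange(.data$class_id, dplyr::desc(.data$percent))
}

#' Fisher-exact functional enrichment of class closures
#'
#' Tests, per (effector class, annotation category) pair, whether the
#' class-weighted protein counts are enriched or depleted relative to a
#' reference proteome annotation. Weighted counts are rounded (half away from
#' zero, configurable) to integers before entering a two-sided Fisher's exact
#' test on the 2x2 table `[in-class in-category, in-class rest; reference
#' in-category, reference rest]`. Raw p-values are flagged at the 0.05
#' convention and Benjamini-Hochberg adjusted p-values are reported alongside.
#'
#' @inheritParams weighted_profile
#' @param reference Annotation table of the full reference proteome (column
#'   `symbol` plus the vocabulary column); its vocabulary must contain every
#'   category seen in the class profiles.
#' @param rounding `"half_away"` (default) or `"half_even"` (banker's
#'   rounding) for converting weighted counts to integers.
#' @return A `ras_enrichment` tibble with one row per (class, category):
#'   `class_id`, `category`, `weighted_count`, `rounded_count`, `class_total`,
#'   `ref_count`, `ref_total`, `fold`, `odds_ratio`, `p_value`, `p_adjusted`,
#'   `significant_05`, `direction`, `degenerate`.
#' @export
fisher_enrichment <- function(weights, annotations, reference,
                              vocabulary = "process15",
                              rounding = c("half_away", "half_even")) {
  rounding <- arg_match(rounding)
  require_columns(reference, c("symbol", vocabulary), "reference annotation")
  joined <- join_category(weights, annotations, vocabulary)
  categories <- sort(unique(reference[[vocabulary]]))
  extra <- setdiff(unique(joined$category), categories)
  if (length(extra) > 0) {
    stop_config("categor%s absent from the reference vocabulary: %s",
                if (length(extra) > 1) "ies" else "y",
                paste(extra, collapse = ", "))
  }
  ref_counts <- table(factor(reference[[vocabulary]], levels = categories))
  ref_total <- nrow(reference)
  round_fun <- if (rounding == "half_away") round_half_away else round

  grid <- joined %>%
    group_by(class_id = .data$class_id,
             category = factor(.data$category, levels = categories)) %>%
    summarise(weighted_count = sum(.data$weight), .groups = "drop") %>%
    tidyr::complete(class_id = unique(joined$class_id),
                    category = factor(categories, levels = categories),
                    fill = list(weighted_count = 0)) %>%
    mutate(category = as.character(.data$category),
           rounded_count = as.integer(round_fun(.data$weighted_count)))

  grid <- grid %>%
    group_by(.data$class_id) %>%
    mutate(class_total = sum(.data$rounded_count)) %>%
    ungroup() %>%
    filter(.data$class_total > 0) %>%
    mutate(ref_count = as.integer(ref_counts[.data$category]),
           ref_total = ref_total)

  res <- grid %>%
    mutate(
      fold = (.data$rounded_count / .data$class_total) /
        (.data$ref_count / .data$ref_total),
      stats = purrr::pmap(list(.data$rounded_count, .data$class_total,
                               .data$ref_count, .data$ref_total),
                          function(a, ct, rc, rt) {
                            b <- ct - a
                            d <- rt - rc
                            tab <- matrix(c(a, b, rc, d), nrow = 2)
                            degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
                            if (degenerate) {
                              list(p = 1, or = NA_real_, degenerate = TRUE)
                            } else {
                              ft <- fisher.test(tab, alternative = "two.sided")
                              # exact p can exceed 1 by floating error
                              list(p = min(1, ft$p.value),
                                   or = (a * d) / (b * rc),
                                   degenerate = FALSE)
                            }
                          })
    ) %>%
    mutate(p_value = purrr::map_dbl(.data$stats, "p"),
           odds_ratio = purrr::map_dbl(.data$stats, "or"),
           degenerate = purrr::map_lgl(.data$stats, "degenerate")) %>%
    select(-"stats") %>%
    mutate(p_adjusted = p.adjust(.data$p_value, method = "BH"),
           significant_05 = .data$p_value < 0.05,
           direction = dplyr::case_when(
             .data$fold > 1 ~ "enriched",
             .data$fold < 1 ~ "depleted",
             TRUE ~ "none"
           )) %>%
    arrange(.data$class_id, .data$category)
  class(res) <- c("ras_enrichment", class(res))
  res
}

#' @rdname fisher_enrichment
#' @param object A `ras_enrichment` table.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.ras_enrichment <- function(object, ...) {
  df <- mutate(as_tibble(object),
               star = ifelse(.data$significant_05, "*", ""))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$class_id),
                                   y = .data$category,
                                   fill = log2(pmax(.data$fold, 1 / 64)))) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$star), size = 3) +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick",
                                  midpoint = 0, name = "log2 fold") +
    ggplot2::labs(x = "effector class", y = NULL,
                  title = "Class-normalized functional enrichment (* raw p < 0.05)") +
    ggplot2::theme_minimal()
}
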