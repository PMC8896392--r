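#' The default Ras effector roster
#'
#' The 43 high-confidence Ras effectors (proteins with a Ras-binding domain
#' that bind active RasGTP directly, or are predicted to be in complex with it
#' in significant amounts) grouped into 12 functional pathway classes. These
#' are the layer-0 nodes from which the network is expanded.
#'
#' @return A tibble with columns `effector` (gene symbol), `class_id`
#'   (integer 1..12) and `class_name`.
#' @examples
#' ras_effector_roster()
#' @export
ras_effector_roster <- function() {
  classes <- list(
    list(1L,  "RAF-MEK-ERK signaling",
         c("ARAF", "BRAF", "RAF1")),
    list(2L,  "PI3K-AKT signaling",
         c("PIK3CA", "PIK3CB", "PIK3CD", "PIK3CG", "PIK3C2B", "PIK3C2A")),
    list(3L,  "RalGEF-Ral-PLD-Sec5 signaling",
         c("RALGDS", "RGL1", "RGL2")),
    list(4L,  "Afadin-Actin-cadherin signaling",
         c("AFDN")),
    list(5L,  "PLCe-DAG-IP3 signaling",
         c("PLCE1")),
    list(6L,  "RIN-ABL-RAB signaling",
         c("RIN1", "RIN2", "RIN3", "SNX27")),
    list(7L,  "RhoGEF-RAC-PAK signaling",
         c("TIAM1", "ARHGAP20", "ARAP1", "ARAP2", "DGKQ")),
    list(8L,  "RASSF-MST-Hippo signaling",
         c("RASSF1", "RASSF2", "RASSF3", "RASSF4", "RASSF5", "RASSF6",
           "RASSF7", "RASSF8")),
    list(9L,  "RapGEF-RAP signaling",
         c("RAPGEF2", "RAPGEF3", "RAPGEF4", "RAPGEF5", "RAPGEF6",
           "APBB1IP", "RAPH1")),
    list(10L, "Myosin-Actin signaling",
         c("MYO9B")),
    list(11L, "RGS-GPCR signaling",
         c("RGS12")),
    list(12L, "RTK-Grb signaling",
         c("GRB7", "GRB10", "GRB14"))
  )
  purrr::map_dfr(classes, function(cl) {
    tibble(effector = cl[[3]], class_id = cl[[1]], class_name = cl[[2]])
  })
}

#' Validate an effector roster table
#'
#' @param roster A data frame with columns `effector`, `class_id` and
#'   optionally `class_name`.
#' @return The roster as a tibble with normalized symbols, invisibly checked:
#'   non-empty, each effector in exactly one class, integer class ids.
#' @export
as_effector_roster <- function(roster) {
  require_columns(roster, c("effector", "class_id"), "effector roster")
  roster <- as_tibble(roster)
  roster$effector <- normalize_symbols(roster$effector)
  roster$class_id <- as.integer(roster$class_id)
  if (!"class_name" %in% names(roster)) {
    roster$class_name <- paste0("class ", roster$class_id)
  }
  if (nrow(roster) == 0) stop_config("effector roster is empty")
  if (anyDuplicated(roster$effector)) {
    stop_config("effector(s) assigned to more than one class: %s",
                join_set(roster$effector[duplicated(roster$effector)]))
  }
  if (any(is.na(roster$class_id))) stop_config("roster class_id must be integer")
  roster
}
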