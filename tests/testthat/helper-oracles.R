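# Independent oracles: brute-force re-implementations of the core definitions,
# deliberately sharing no code with the package internals.

# Exhaustive path-enumeration layering: protein p is a layer-k member iff an
# admitted expansion chain of length k exists from some effector to p. Admitted
# edges from p at step k: directed records with source p; if p has no directed
# source-record (and k == 1 or undirected_at_depth), undirected records
# touching p, oriented p -> partner. Self-loops dropped.
oracle_layering <- function(roster, records, max_depth = 3,
                            undirected_at_depth = FALSE) {
  records <- records[records$source != records$target, , drop = FALSE]
  directed <- records[records$directed, , drop = FALSE]
  undirected <- records[!records$directed, , drop = FALSE]
  has_dir <- unique(directed$source)

  expand_from <- function(p, k) {
    tg <- directed$target[directed$source == p]
    if ((k == 1 || undirected_at_depth) && !(p %in% has_dir)) {
      tg <- c(tg,
              undirected$target[undirected$source == p],
              undirected$source[undirected$target == p])
    }
    setdiff(unique(tg), p)
  }

  members <- new.env(parent = emptyenv())  # "protein\tlayer"
  edges <- new.env(parent = emptyenv())    # "s\tt\tk" -> class id set
  visited <- new.env(parent = emptyenv())  # "p\tk\tcid"

  walk <- function(p, k, cid) {
    if (k > max_depth) return(invisible())
    for (t in expand_from(p, k)) {
      members[[paste(t, k, sep = "\t")]] <- TRUE
      ek <- paste(p, t, k, sep = "\t")
      edges[[ek]] <- union(edges[[ek]], cid)
      vk <- paste(t, k, cid, sep = "\t")
      if (is.null(visited[[vk]])) {
        visited[[vk]] <- TRUE
        walk(t, k + 1, cid)
      }
    }
  }
  for (i in seq_len(nrow(roster))) {
    walk(roster$effector[i], 1L, roster$class_id[i])
  }

  mem_keys <- ls(members)
  mem <- if (length(mem_keys) > 0) {
    parts <- strsplit(mem_keys, "\t", fixed = TRUE)
    data.frame(protein = vapply(parts, `[`, "", 1),
               layer = as.integer(vapply(parts, `[`, "", 2)))
  } else {
    data.frame(protein = character(), layer = integer())
  }
  mem <- rbind(mem, data.frame(protein = roster$effector, layer = 0L))

  edge_keys <- ls(edges)
  ed <- if (length(edge_keys) > 0) {
    parts <- strsplit(edge_keys, "\t", fixed = TRUE)
    data.frame(source = vapply(parts, `[`, "", 1),
               target = vapply(parts, `[`, "", 2),
               layer = as.integer(vapply(parts, `[`, "", 3)),
               classes = vapply(edge_keys, function(k) {
                 paste(sort(as.character(edges[[k]])), collapse = ";")
               }, "", USE.NAMES = FALSE))
  } else {
    data.frame(source = character(), target = character(), layer = integer(),
               classes = character())
  }

  closures <- lapply(sort(unique(roster$class_id)), function(cid) {
    down <- ed[vapply(strsplit(ed$classes, ";", fixed = TRUE),
                      function(s) as.character(cid) %in% s, logical(1)), ]
    sort(unique(down$target))
  })
  names(closures) <- as.character(sort(unique(roster$class_id)))
  list(members = mem, edges = ed, closures = closures)
}

# Brute-force feedback scan: every distinct edge crossed with every
# layer-membership combination of its endpoints.
oracle_feedbacks <- function(network) {
  members <- network$members
  layers_of <- split(members$layer, members$protein)
  edges <- unique(network$edges[, c("source", "target")])
  hits <- character()
  for (i in seq_len(nrow(edges))) {
    u <- edges$source[i]; v <- edges$target[i]
    for (lu in layers_of[[u]]) {
      for (lv in layers_of[[v]]) {
        if (lu >= 2 && lv <= 1 && lu - lv >= 2) {
          hits <- c(hits, paste(u, v, lv, sep = "\t"))
        }
      }
    }
  }
  sort(unique(hits))
}

loop_keys <- function(loops) {
  sort(paste(loops$downstream_source, loops$upstream_target, loops$target_layer,
             sep = "\t"))
}

# Two-sided Fisher exact p by direct hypergeometric summation (log-space
# choose()), for the table rbind(c(a, b), c(c, d)).
oracle_fisher_p <- function(a, b, c, d) {
  k <- a + b          # first-row margin
  m <- a + c          # first-column margin
  n <- b + d
  N <- a + b + c + d
  lo <- max(0L, k - n)
  hi <- min(k, m)
  xs <- lo:hi
  logp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(N, k)
  p_obs <- logp[xs == a]
  sum(exp(logp[logp <= p_obs + 1e-7]))
}

# Random source-record tables for oracle comparisons: mixed directed and
# undirected records over a small symbol universe.
random_records <- function(seed, n_nodes = 30, n_edges = 60, n_effectors = 4,
                           n_classes = 3, p_undirected = 0.3) {
  set.seed(seed)
  syms <- sprintf("P%02d", seq_len(n_nodes))
  roster <- tibble::tibble(
    effector = syms[seq_len(n_effectors)],
    class_id = rep_len(seq_len(n_classes), n_effectors)
  )
  records <- tibble::tibble(
    source = sample(syms, n_edges, replace = TRUE),
    target = sample(syms, n_edges, replace = TRUE),
    directed = stats::runif(n_edges) > p_undirected
  )
  list(roster = roster, records = rasnet::as_source_records(records))
}
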