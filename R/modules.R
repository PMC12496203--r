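#' Select the most strongly regulated genes per treatment
#'
#' For each condition's DE-vs-T0 table, genes passing `p < p_thresh` and
#' `lfc > lfc_thresh` (up) or `lfc < -lfc_thresh` (down) are ranked by fold
#' change and the top `n_up` / `n_down` retained; ties at the cut are broken
#' by gene id for determinism. The union over conditions (with per-condition
#' membership) feeds module clustering.
#'
#' @param de_list Named list of DE tibbles (one per condition, vs T0).
#' @param n_up,n_down Genes taken per direction and condition.
#' @param p_thresh,lfc_thresh Eligibility thresholds (raw p, absolute lfc).
#' @return Tibble: `gene`, `condition`, `direction`, `lfc`. Attribute
#'   `shortfall` records conditions with fewer passing genes than requested.
#' @export
select_top_genes <- function(de_list, n_up = 200, n_down = 200,
                             p_thresh = 0.05, lfc_thresh = 1.5) {
  stopifnot(is.list(de_list), length(de_list) > 0, !is.null(names(de_list)))
  shortfall <- list()
  rows <- purrr::imap(de_list, function(de, cond) {
    up <- de %>% filter(.data$p < p_thresh, .data$lfc > lfc_thresh) %>%
      arrange(dplyr::desc(.data$lfc), .data$gene) %>% head(n_up)
    dn <- de %>% filter(.data$p < p_thresh, .data$lfc < -lfc_thresh) %>%
      arrange(.data$lfc, .data$gene) %>% head(n_down)
    if (nrow(up) < n_up || nrow(dn) < n_down) {
      shortfall[[cond]] <<- c(up = nrow(up), down = nrow(dn))
    }
    dplyr::bind_rows(
      up %>% mutate(condition = cond, direction = "up"),
      dn %>% mutate(condition = cond, direction = "down")) %>%
      select("gene", "condition", "direction", "lfc")
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "shortfall") <- shortfall
  out
}

#' K-means gene modules with gap-statistic K selection
#'
#' Genes (rows of an LFC matrix over conditions) are clustered with K-means
#' (`nstart` random restarts) for each candidate K; the number of modules is
#' chosen by the gap statistic, `Gap(k) = E*[log W_k] - log W_k` with B
#' uniform reference draws over the per-feature bounding box, taking the
#' smallest k with `Gap(k) >= Gap(k+1) - s_{k+1}` (via [cluster::clusGap()]
#' with `spaceH0 = "original"` and the `"Tibs2001SEmax"` rule). Module scores
#' are per-module median LFC per condition.
#'
#' @param lfc_matrix Numeric matrix, selected genes x conditions (rownames =
#'   gene ids).
#' @param k_max Largest K considered.
#' @param B Reference draws for the gap statistic.
#' @param seed Seed (clustering and reference draws).
#' @param nstart K-means restarts.
#' @return List of class `combiphen_modules`: `assignments` (tibble `gene`,
#'   `module`), `k`, `gap_curve` (tibble `k`, `logW`, `E_logW`, `gap`, `se`),
#'   `module_scores` (tibble `module`, `condition`, `score`).
#' @export
cluster_gene_modules <- function(lfc_matrix, k_max = 10, B = 50, seed = 1,
                                 nstart = 10) {
  x <- as.matrix(lfc_matrix)
  if (is.null(rownames(x))) rownames(x) <- sprintf("row%05d", seq_len(nrow(x)))
  n_distinct_rows <- nrow(unique(x))
  if (n_distinct_rows <= 1) {
    assignments <- tibble::tibble(gene = rownames(x), module = 1L)
    scores <- tibble::tibble(module = 1L, condition = colnames(x),
                             score = unname(apply(x, 2, median)))
    return(structure(list(assignments = assignments, k = 1L,
                          gap_curve = NULL, module_scores = scores),
                     class = "combiphen_modules"))
  }
  k_max <- max(2, min(k_max, n_distinct_rows, nrow(x) - 1))
  km_fun <- function(x, k) kmeans(x, k, nstart = nstart, iter.max = 50)
  set.seed(derive_seed(seed, "gap"))
  gap <- cluster::clusGap(x, FUNcluster = km_fun, K.max = k_max, B = B,
                          spaceH0 = "original", verbose = FALSE)
  tab <- gap$Tab
  k <- cluster::maxSE(tab[, "gap"], tab[, "SE.sim"], method = "Tibs2001SEmax")
  set.seed(derive_seed(seed, "gap-final"))
  cl <- if (k == 1) rep(1L, nrow(x)) else km_fun(x, k)$cluster
  assignments <- tibble::tibble(gene = rownames(x), module = as.integer(cl))
  scores <- tibble::as_tibble(as.data.frame(x)) %>%
    mutate(module = as.integer(cl)) %>%
    tidyr::pivot_longer(-"module", names_to = "condition", values_to = "lfc") %>%
    group_by(.data$module, .data$condition) %>%
    summarise(score = median(.data$lfc), .groups = "drop")
  structure(list(assignments = assignments, k = as.integer(k),
                 gap_curve = tibble::tibble(k = seq_len(nrow(tab)),
                                            logW = tab[, "logW"],
                                            E_logW = tab[, "E.logW"],
                                            gap = tab[, "gap"],
                                            se = tab[, "SE.sim"]),
                 module_scores = scores),
            class = "combiphen_modules")
}

#' Pairwise Pearson correlation of treatment LFC profiles
#'
#' Reporting utility over a selected-gene LFC matrix: correlations between
#' every pair of conditions, flagging high-similarity pairs.
#'
#' @param lfc_matrix Genes x conditions matrix.
#' @param threshold Correlation above which a pair is flagged.
#' @return Tibble: `cond_a`, `cond_b`, `r`, `high_similarity`.
#' @export
lfc_correlation <- function(lfc_matrix, threshold = 0.7) {
  cm <- cor(as.matrix(lfc_matrix))
  pairs <- utils::combn(colnames(cm), 2)
  tibble::tibble(cond_a = pairs[1, ], cond_b = pairs[2, ],
                 r = cm[cbind(pairs[1, ], pairs[2, ])]) %>%
    mutate(high_similarity = .data$r > threshold)
}
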