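#' Read / write cell-track tables
#'
#' Track CSVs use the columns `cell_id, frame, x_px, y_px, area_px2, field,
#' condition, replicate`; in memory the package uses `x`, `y`, `area` plus a
#' derived time column `t` (hours).
#'
#' @param path File path.
#' @param frame_interval Hours per frame used to reconstruct `t` on read.
#' @param field_size Optional field side (px) stored as an attribute.
#' @return [read_tracks()] returns the track tibble.
#' @export
read_tracks <- function(path, frame_interval = 0.5, field_size = NULL) {
  d <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("cell_id", "frame", "x_px", "y_px", "area_px2", "field",
            "condition", "replicate")
  if (!all(need %in% names(d))) {
    abort(paste0("track CSV must have columns: ", paste(need, collapse = ", ")))
  }
  out <- d %>% mutate(t = .data$frame * frame_interval) %>%
    rename(x = "x_px", y = "y_px", area = "area_px2") %>%
    select("cell_id", "frame", "t", "x", "y", "area", "field", "condition",
           "replicate")
  attr(out, "frame_interval") <- frame_interval
  if (!is.null(field_size)) attr(out, "field_size") <- field_size
  out
}

#' @rdname read_tracks
#' @param tracks Track tibble.
#' @export
write_tracks <- function(tracks, path) {
  out <- tracks %>%
    select("cell_id", "frame", x_px = "x", y_px = "y", area_px2 = "area",
           "field", "condition", "replicate")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write gene x sample count matrices with a sample sheet
#'
#' Counts are stored as TSV with gene ids in the first column; the sample
#' sheet as TSV with `sample_id`, `condition`, `replicate` (and optionally
#' `timepoint`).
#'
#' @param counts_path,samples_path File paths.
#' @return [read_counts()] returns `list(counts, samples)`.
#' @export
read_counts <- function(counts_path, samples_path) {
  d <- read.delim(counts_path, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(d[, -1, drop = FALSE])
  rownames(counts) <- d[[1]]
  samples <- tibble::as_tibble(read.delim(samples_path, stringsAsFactors = FALSE))
  if (!all(colnames(counts) %in% samples$sample_id)) {
    abort("sample sheet does not cover every count column.")
  }
  list(counts = counts, samples = samples)
}

#' @rdname read_counts
#' @param counts Count matrix; `samples` its sample sheet.
#' @param samples Sample sheet tibble.
#' @export
write_counts <- function(counts, samples, counts_path, samples_path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(samples, samples_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(counts_path)
}

#' Read / write differential-expression tables
#'
#' TSV with columns `gene`, `lfc`, `p`, `q`, `contrast`; reading validates
#' via [import_de_table()].
#'
#' @param path File path.
#' @export
read_de_table <- function(path) {
  import_de_table(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_de_table
#' @param de DE tibble.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialise a PLS1 model to JSON
#'
#' Stores the weights, loadings, y-loadings, standardized coefficients and
#' the full preprocessing record, enough to reconstruct predictions.
#'
#' @param fit A [fit_pls1()] object.
#' @param path Output path.
#' @export
write_pls_model <- function(fit, path) {
  stopifnot(inherits(fit, "pls1_fit"))
  obj <- list(ncomp = fit$ncomp,
              genes = fit$genes,
              weights = unname(as.data.frame(fit$W)),
              loadings = unname(as.data.frame(fit$P)),
              y_loadings = fit$y_loadings,
              ssy = fit$ssy,
              beta_std = unname(fit$beta_std),
              x_center = unname(fit$x_center),
              x_scale = unname(fit$x_scale),
              y_center = fit$y_center, y_scale = fit$y_scale)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
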