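# Genomic relationship matrices and the sliding-window grid.

#' Build an allele-frequency-scaled genomic relationship matrix
#'
#' `G = Wc Wc' / sum_i 2 p_i (1 - p_i)` over the selected markers, where
#' `Wc` is the column-centered marker matrix and `p_i` the frequency of the
#' +1 allele, estimated from the codes as the mean of `(x + 1) / 2` over
#' non-missing entries (for dominant presence/absence markers this is the
#' presence frequency). Missing entries are mean-imputed before centering;
#' monomorphic markers are dropped from both the numerator and the scaling
#' sum. The `2 p q` denominator assumes dosage coding; for dominant columns
#' it is a deliberate heuristic kept as the default for fidelity to the
#' construction, and `scale = "empirical"` replaces the scaling sum by the
#' summed empirical column variances instead.
#'
#' @param genotypes a [genotype_matrix()].
#' @param marker_subset optional marker ids or column indices.
#' @param scale `"2pq"` (default) or `"empirical"`.
#' @return object of class `grm`: `matrix`, `accession_ids`, `scaling`
#'   (the denominator), `markers_used`.
#' @export
build_grm <- function(genotypes, marker_subset = NULL, scale = c("2pq", "empirical")) {
  scale <- match.arg(scale)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  W <- genotypes$values
  if (nrow(W) < 2L) stop_format("need at least 2 accessions to build a GRM")
  if (!is.null(marker_subset)) {
    if (is.character(marker_subset)) marker_subset <- match(marker_subset, colnames(W))
    if (anyNA(marker_subset)) stop_format("marker_subset contains unknown markers")
    W <- W[, marker_subset, drop = FALSE]
  }
  W <- mean_impute(W)
  p <- (colMeans(W) + 1) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop_format("all selected markers are monomorphic")
  W <- W[, poly, drop = FALSE]
  p <- p[poly]
  Wc <- sweep(W, 2L, colMeans(W))
  denom <- if (scale == "2pq") sum(2 * p * (1 - p)) else sum(apply(W, 2L, var))
  G <- tcrossprod(Wc) / denom
  structure(list(matrix = G, accession_ids = rownames(W), scaling = denom,
                 markers_used = colnames(W), scale = scale),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("GRM: %d accessions, %d markers, scaling sum %.3f, mean diagonal %.3f\n",
              nrow(x$matrix), length(x$markers_used), x$scaling,
              mean(diag(x$matrix))))
  invisible(x)
}

#' Regional genomic relationship matrix for one window
#'
#' Same construction as [build_grm()] restricted to the markers inside a
#' window; the scaling sum runs over the window markers only.
#'
#' @param genotypes a [genotype_matrix()].
#' @param window one row of a [window_grid()] (or a list with `chromosome`,
#'   `start_bp`, `end_bp`).
#' @param scale as in [build_grm()].
#' @return a `grm`.
#' @export
build_regional_grm <- function(genotypes, window, scale = c("2pq", "empirical")) {
  scale <- match.arg(scale)
  idx <- window_markers(genotypes$map, window)
  if (length(idx) == 0L) stop_format("window contains no markers")
  build_grm(genotypes, marker_subset = idx, scale = scale)
}

window_markers <- function(map, window) {
  which(map$chromosome == window$chromosome &
          map$position_bp >= window$start_bp &
          map$position_bp < window$end_bp)
}

#' Sliding-window grid over the genome
#'
#' Per chromosome, windows of `length_bp` start at 0 and advance by
#' `step_bp` while `start < chrom_length - step_bp`; the last window is
#' truncated at the chromosome end (half-open intervals `[start, end)`).
#' Windows holding fewer than `min_markers` markers are dropped.
#'
#' @param map marker map (0-based positions), e.g. `genotypes$map`.
#' @param length_bp window length (default 2 Mb).
#' @param step_bp step between window starts (default 1 Mb).
#' @param min_markers minimum markers per retained window (default 2).
#' @param chrom_lengths_bp optional named/indexed chromosome lengths; when
#'   absent, the last marker position + 1 is used.
#' @return data.frame of class `window_grid` with columns `window_id`,
#'   `chromosome`, `start_bp`, `end_bp`, `n_markers` and a list column
#'   `markers` of marker-map row indices.
#' @export
window_grid <- function(map, length_bp = 2e6, step_bp = 1e6, min_markers = 2L,
                        chrom_lengths_bp = NULL) {
  if (step_bp > length_bp) stop_format("step_bp must not exceed length_bp")
  chroms <- sort(unique(map$chromosome))
  rows <- list()
  for (chr in chroms) {
    on_chr <- which(map$chromosome == chr)
    L <- if (!is.null(chrom_lengths_bp)) chrom_lengths_bp[chr]
         else max(map$position_bp[on_chr]) + 1
    starts <- seq(0, by = step_bp, length.out = max(1, ceiling((L - step_bp) / step_bp)))
    starts <- starts[starts < max(L - step_bp, 1)]
    if (length(starts) == 0L) starts <- 0
    for (s in starts) {
      e <- min(s + length_bp, L)
      idx <- on_chr[map$position_bp[on_chr] >= s & map$position_bp[on_chr] < e]
      rows[[length(rows) + 1L]] <-
        list(chromosome = chr, start_bp = s, end_bp = e,
             n_markers = length(idx), markers = idx)
    }
  }
  out <- data.frame(chromosome = vapply(rows, `[[`, 0, "chromosome"),
                    start_bp = vapply(rows, `[[`, 0, "start_bp"),
                    end_bp = vapply(rows, `[[`, 0, "end_bp"),
                    n_markers = vapply(rows, `[[`, 0, "n_markers"))
  out$markers <- lapply(rows, `[[`, "markers")
  out <- out[out$n_markers >= min_markers, , drop = FALSE]
  out <- out[order(out$chromosome, out$start_bp), , drop = FALSE]
  out$window_id <- sprintf("W%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  class(out) <- c("window_grid", "data.frame")
  out[, c("window_id", "chromosome", "start_bp", "end_bp", "n_markers", "markers")]
}
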