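# Tabular file formats.
#
# Genotype matrix: tab-separated, header "accession" then one column per
# marker id; SNP entries in {-1, 0, 1}, DArT entries in {-1, 1}; missing "NA".
# Marker map: tab-separated with columns marker_id, chromosome, position_bp,
# marker_type. Positions are 1-based bp in files and 0-based internally, so
# window arithmetic is half-open [start, end).

MARKER_TYPES <- c("SNP", "DART")

#' Construct a genotype matrix object
#'
#' Bundles a numeric accessions x markers matrix with its marker map and
#' validates the coding: SNP columns must be in \{-1, 0, 1, NA\} and DArT
#' (dominant presence/absence) columns in \{-1, 1, NA\}; map columns must be
#' sorted by position within chromosome and match the matrix column order.
#'
#' @param values numeric matrix, accessions in rows (rownames = accession
#'   ids), markers in columns (colnames = marker ids).
#' @param map data.frame with columns `marker_id`, `chromosome` (integer),
#'   `position_bp` (0-based bp), `marker_type` ("SNP" or "DART").
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values, map) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  map <- as.data.frame(map)
  need <- c("marker_id", "chromosome", "position_bp", "marker_type")
  if (!all(need %in% names(map)))
    stop_format("marker map must have columns: %s", paste(need, collapse = ", "))
  map$marker_id <- as.character(map$marker_id)
  map$chromosome <- as.integer(map$chromosome)
  map$position_bp <- as.numeric(map$position_bp)
  map$marker_type <- toupper(as.character(map$marker_type))
  if (anyDuplicated(map$marker_id))
    stop_format("duplicate marker ids in map (e.g. '%s')",
                map$marker_id[duplicated(map$marker_id)][1L])
  if (!all(map$marker_type %in% MARKER_TYPES))
    stop_format("unknown marker_type '%s' (expected SNP or DART)",
                setdiff(map$marker_type, MARKER_TYPES)[1L])
  if (any(map$position_bp < 0)) stop_format("negative marker position in map")
  ord <- order(map$chromosome, map$position_bp)
  if (!identical(ord, seq_len(nrow(map)))) map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  if (is.null(colnames(values)))
    stop_format("genotype matrix must carry marker ids as column names")
  if (!setequal(colnames(values), map$marker_id))
    stop_format("marker ids in matrix and map do not match (%d vs %d markers)",
                ncol(values), nrow(map))
  values <- values[, map$marker_id, drop = FALSE]
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("ACC%04d", seq_len(nrow(values)))
  validate_codes(values, map)
  structure(list(accession_ids = rownames(values), values = values, map = map),
            class = "genotype_matrix")
}

validate_codes <- function(values, map) {
  is_snp <- map$marker_type == "SNP"
  check_set <- function(cols, allowed, label) {
    v <- values[, cols, drop = FALSE]
    bad <- !(v %in% allowed) & !is.na(v)
    if (any(bad)) {
      idx <- which(matrix(bad, nrow(v)), arr.ind = TRUE)[1L, ]
      stop_format("invalid %s code %s at accession '%s', marker '%s'",
                  label, format(v[idx[1L], idx[2L]]),
                  rownames(v)[idx[1L]], colnames(v)[idx[2L]])
    }
  }
  if (any(is_snp)) check_set(map$marker_id[is_snp], c(-1, 0, 1), "SNP")
  if (any(!is_snp)) check_set(map$marker_id[!is_snp], c(-1, 1), "DArT")
  invisible(TRUE)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  tab <- table(x$map$marker_type)
  cat(sprintf("genotype_matrix: %d accessions x %d markers (%s) on %d chromosome(s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
              length(unique(x$map$chromosome))))
  miss <- mean(is.na(x$values))
  cat(sprintf("  missing: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Read a genotype matrix and its marker map
#'
#' @param path tab-separated genotype file: header row `accession` followed
#'   by marker ids; one row per accession; missing entries coded `NA`.
#' @param map_path tab-separated map file with columns marker_id,
#'   chromosome, position_bp (1-based), marker_type.
#' @return a [genotype_matrix()] object (positions converted to 0-based).
#' @export
read_genotypes <- function(path, map_path) {
  map <- read.delim(map_path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("marker_id", "chromosome", "position_bp", "marker_type")
  if (!all(need %in% names(map)))
    stop_format("map file '%s' lacks required columns: %s", map_path,
                paste(setdiff(need, names(map)), collapse = ", "))
  map$position_bp <- map$position_bp - 1  # 1-based on disk, 0-based in memory
  tab <- read.delim(path, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (names(tab)[1L] != "accession")
    stop_format("genotype file '%s' must start with an 'accession' column", path)
  ids <- as.character(tab[[1L]])
  values <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(values))
    stop_format("non-numeric genotype code in '%s'", path)
  rownames(values) <- ids
  genotype_matrix(values, map)
}

#' Write a genotype matrix and marker map to tab-separated files
#'
#' Inverse of [read_genotypes()]; positions are written 1-based.
#'
#' @param gm a `genotype_matrix`.
#' @param path,map_path output file paths.
#' @export
write_genotypes <- function(gm, path, map_path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  map <- gm$map
  map$position_bp <- map$position_bp + 1
  write.table(map, map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- data.frame(accession = rownames(gm$values), gm$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, map_path))
}

#' Read an augmented-block phenotype table
#'
#' @param path tab-separated file with columns `accession`, `environment`,
#'   `block`, `is_check` (0/1) and at least one trait column; trait values
#'   are reals with `NA` allowed.
#' @return a data.frame of class `pheno_table`; trait column names are kept
#'   in `attr(, "traits")`.
#' @export
read_phenotypes <- function(path) {
  tab <- read.delim(path, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  pheno_table(tab)
}

#' Construct/validate a phenotype table
#'
#' @param tab data.frame with design columns `accession`, `environment`,
#'   `block`, `is_check` plus one or more numeric trait columns.
#' @return the validated table, class `pheno_table`.
#' @export
pheno_table <- function(tab) {
  need <- c("accession", "environment", "block", "is_check")
  if (!all(need %in% names(tab)))
    stop_format("phenotype table lacks required columns: %s",
                paste(setdiff(need, names(tab)), collapse = ", "))
  traits <- setdiff(names(tab), need)
  if (length(traits) == 0L)
    stop_format("phenotype table has no trait columns")
  for (tr in traits) tab[[tr]] <- as.numeric(tab[[tr]])
  tab$is_check <- as.logical(tab$is_check)
  key <- paste(tab$accession, tab$environment, tab$block, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop_format("duplicate design row: accession '%s', environment '%s', block '%s'",
                tab$accession[d], tab$environment[d], tab$block[d])
  }
  if (any(tab$is_check)) {
    has_check <- tapply(tab$is_check, paste(tab$environment, tab$block), any)
    if (!all(has_check))
      warn_format("%d block(s) contain no check plots", sum(!has_check))
  }
  attr(tab, "traits") <- traits
  class(tab) <- c("pheno_table", "data.frame")
  tab
}

#' Write a phenotype table
#' @param pheno a `pheno_table`.
#' @param path output path (tab-separated).
#' @export
write_phenotypes <- function(pheno, path) {
  out <- as.data.frame(pheno)
  out$is_check <- as.integer(out$is_check)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write result tables with a deterministic layout
#'
#' Writes each table in `tables` to `<out_dir>/<name>.tsv`. Known result
#' kinds are sorted canonically first: GWAS tables by (chromosome,
#' position), regional-scan tables by (chromosome, window start), so that
#' re-running on the same inputs produces byte-identical files.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_format("cannot create output directory '%s'", out_dir)
  paths <- character(0)
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    if (all(c("chromosome", "position_bp") %in% names(tab))) {
      tab <- tab[order(tab$chromosome, tab$position_bp), , drop = FALSE]
    } else if (all(c("chromosome", "start_bp") %in% names(tab))) {
      tab <- tab[order(tab$chromosome, tab$start_bp), , drop = FALSE]
    }
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
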