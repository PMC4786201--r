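#' Read a per-cytosine methylation count table
#'
#' Parses one sample's per-cytosine counts from a tab-separated file in one of
#' three common dialects and returns a sorted, deduplicated `MethylomeSample`.
#'
#' Dialects:
#' * `generic`: header `chrom pos strand context n_meth n_total`.
#' * `cx_report`: headerless 7 columns in Bismark cytosine-report style
#'   (`chrom pos strand count_meth count_unmeth context tricontext`);
#'   `n_total = count_meth + count_unmeth`.
#' * `methratio`: BSMAP methratio-style header with columns `chrom, pos,
#'   strand, context, ratio, eff_CT_count, C_count, CT_count`; methylated and
#'   total counts are taken from `C_count` and `CT_count`.
#'
#' Coordinates are 1-based; strands are kept separate (symmetric CG sites on
#' opposite strands are two sites). Contexts outside CG/CHG/CHH are mapped to
#' `"unknown"`.
#'
#' @param path Path to the count table.
#' @param dialect One of `"generic"`, `"cx_report"`, `"methratio"`.
#' @param sample_id Sample identifier; defaults to the file name sans
#'   extension.
#' @param context Optional filter: keep only sites in these contexts
#'   (e.g. `"CG"`). Default keeps all contexts pooled.
#' @return A `MethylomeSample`: a `data.table` with columns
#'   `chrom, pos, strand, context, n_meth, n_total`, sorted by
#'   (chrom, pos, strand), with the sample id stored as an attribute.
#' @export
read_counts_table <- function(path,
                              dialect = c("generic", "cx_report", "methratio"),
                              sample_id = NULL, context = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))

  has_header <- dialect != "cx_report"
  raw <- data.table::fread(path, sep = "\t", header = has_header,
                           colClasses = "character", fill = FALSE,
                           blank.lines.skip = FALSE)
  if (nrow(raw) == 0L) return(new_methylome_sample(empty_sites(), sample_id))

  line_of <- function(i) i + as.integer(has_header)  # 1-based file line

  need <- switch(dialect,
    generic   = c("chrom", "pos", "strand", "context", "n_meth", "n_total"),
    methratio = c("chrom", "pos", "strand", "context", "C_count", "CT_count"),
    cx_report = NULL)
  if (dialect == "cx_report") {
    if (ncol(raw) != 7L)
      stop("cx_report dialect expects 7 columns, got ", ncol(raw), call. = FALSE)
    data.table::setnames(raw, c("chrom", "pos", "strand", "count_meth",
                                "count_unmeth", "context", "tricontext"))
  } else {
    missing_cols <- setdiff(need, names(raw))
    if (length(missing_cols))
      stop("missing column(s) in ", dialect, " table: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  to_int <- function(col, colname) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad))
      stop(sprintf("malformed value in column '%s' at line %d of %s",
                   colname, line_of(bad[1L]), path), call. = FALSE)
    as.integer(v)
  }

  pos <- to_int("pos", "pos")
  bad_pos <- which(pos < 1L)
  if (length(bad_pos))
    stop(sprintf("pos < 1 at line %d of %s", line_of(bad_pos[1L]), path),
         call. = FALSE)

  n_meth <- switch(dialect,
    generic   = to_int("n_meth", "n_meth"),
    cx_report = to_int("count_meth", "count_meth"),
    methratio = to_int("C_count", "C_count"))
  n_total <- switch(dialect,
    generic   = to_int("n_total", "n_total"),
    cx_report = to_int("count_meth", "count_meth") +
                to_int("count_unmeth", "count_unmeth"),
    methratio = to_int("CT_count", "CT_count"))

  bad <- which(n_meth > n_total)
  if (length(bad))
    stop(sprintf("n_meth > n_total at line %d of %s", line_of(bad[1L]), path),
         call. = FALSE)

  strand <- raw[["strand"]]
  strand[strand == "."] <- "*"
  bad <- which(!strand %in% c("+", "-", "*"))
  if (length(bad))
    stop(sprintf("invalid strand '%s' at line %d of %s",
                 strand[bad[1L]], line_of(bad[1L]), path), call. = FALSE)

  ctx <- normalize_context(raw[["context"]])
  sites <- data.table::data.table(
    chrom = raw[["chrom"]], pos = pos, strand = strand, context = ctx,
    n_meth = n_meth, n_total = n_total)

  dup <- duplicated(sites, by = c("chrom", "pos", "strand"))
  if (any(dup)) {
    i <- which(dup)[1L]
    stop(sprintf("duplicate site key (%s, %d, %s) at line %d of %s",
                 sites$chrom[i], sites$pos[i], sites$strand[i],
                 line_of(i), path), call. = FALSE)
  }
  if (!is.null(context)) {
    keep_ctx <- context  # avoid data.table scoping on the column name
    sites <- sites[sites$context %in% keep_ctx, ]
  }
  data.table::setorder(sites, chrom, pos, strand)
  new_methylome_sample(sites, sample_id)
}

normalize_context <- function(x) {
  x <- toupper(x)
  x[x %in% c("CPG")] <- "CG"
  x[!x %in% c("CG", "CHG", "CHH")] <- "unknown"
  x
}

empty_sites <- function() {
  data.table::data.table(chrom = character(), pos = integer(),
                         strand = character(), context = character(),
                         n_meth = integer(), n_total = integer())
}

new_methylome_sample <- function(sites, sample_id) {
  stopifnot(all(sites$n_meth <= sites$n_total))
  data.table::setattr(sites, "sample_id", sample_id)
  data.table::setattr(sites, "class",
                      c("MethylomeSample", class(data.table::data.table())))
  sites[]
}

#' @export
print.MethylomeSample <- function(x, ...) {
  cat(sprintf("MethylomeSample '%s': %d sites on %d chromosome(s)\n",
              attr(x, "sample_id"), nrow(x), length(unique(x$chrom))))
  NextMethod()
}

#' Write a MethylomeSample as a generic-dialect count table
#'
#' Inverse of [read_counts_table()] for the `generic` dialect; `write` then
#' `read` round-trips exactly.
#'
#' @param sample A `MethylomeSample`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(sample, path) {
  data.table::fwrite(as.data.frame(sample), path, sep = "\t")
  invisible(path)
}

#' Assemble a multi-sample methylation-level matrix
#'
#' Builds the union-of-sites matrix of methylation levels
#' \eqn{p = n_{meth} / n_{total}} across samples. Where a sample lacks a site
#' (or covers it with zero reads) the level is `NA` ("missing"): missing
#' levels contribute zero entropy downstream and are excluded from pairwise
#' divergences.
#'
#' @param samples A list of `MethylomeSample` objects (at least one).
#' @return A `MethylMatrix`: list with `sites` (a `data.table` of
#'   chrom/pos/strand/context keys, sorted), `levels` and `coverage`
#'   (site-by-sample matrices), and `sample_ids`.
#' @export
build_matrix <- function(samples) {
  if (!is.list(samples) || length(samples) == 0L)
    stop("`samples` must be a non-empty list of MethylomeSample objects",
         call. = FALSE)
  ids <- vapply(seq_along(samples), function(i) {
    attr(samples[[i]], "sample_id") %||% paste0("sample", i)
  }, character(1))
  if (anyDuplicated(ids)) ids <- make.unique(ids)

  keys <- data.table::rbindlist(lapply(samples, function(s)
    s[, c("chrom", "pos", "strand", "context")]))
  # context is informational; key identity is (chrom, pos, strand)
  keys <- unique(keys, by = c("chrom", "pos", "strand"))
  data.table::setorder(keys, chrom, pos, strand)
  keys[, `:=`(.row = .I)]

  n <- nrow(keys)
  levels <- matrix(NA_real_, n, length(samples),
                   dimnames = list(NULL, ids))
  coverage <- matrix(NA_integer_, n, length(samples),
                     dimnames = list(NULL, ids))
  for (j in seq_along(samples)) {
    s <- samples[[j]]
    idx <- keys[s, on = c("chrom", "pos", "strand"), .row]
    coverage[idx, j] <- s$n_total
    p <- ifelse(s$n_total > 0L, s$n_meth / s$n_total, NA_real_)
    levels[idx, j] <- p
  }
  keys[, .row := NULL]
  structure(list(sites = keys[], levels = levels, coverage = coverage,
                 sample_ids = ids),
            class = "MethylMatrix")
}

#' @export
print.MethylMatrix <- function(x, ...) {
  cat(sprintf("MethylMatrix: %d sites x %d samples (%d missing cells)\n",
              nrow(x$levels), ncol(x$levels), sum(is.na(x$levels))))
  cat("samples:", paste(x$sample_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Tile chromosomes into fixed-length genomic regions
#'
#' Splits each chromosome into contiguous, non-overlapping 1-based closed
#' tiles of length `l`; the final tile is truncated at the chromosome end and
#' flagged `partial` so length-sensitive fits can exclude it.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp, or a
#'   two-column data frame `chrom, length`.
#' @param l Tile length in bp (>= 1).
#' @return A `data.table` with columns `chrom, start, end, width, partial`.
#' @export
tile_genome <- function(chrom_sizes, l) {
  if (!is.numeric(l) || length(l) != 1L || l < 1)
    stop("`l` must be a single integer >= 1", call. = FALSE)
  l <- as.integer(l)
  if (is.data.frame(chrom_sizes))
    chrom_sizes <- setNames(as.numeric(chrom_sizes[[2]]),
                            as.character(chrom_sizes[[1]]))
  if (is.null(names(chrom_sizes)) || any(chrom_sizes < 1))
    stop("`chrom_sizes` must be a named vector of positive lengths",
         call. = FALSE)
  tiles <- lapply(names(chrom_sizes), function(ch) {
    size <- as.integer(chrom_sizes[[ch]])
    start <- seq.int(1L, size, by = l)
    end <- pmin(start + l - 1L, size)
    data.table::data.table(chrom = ch, start = start, end = end,
                           width = end - start + 1L)
  })
  out <- data.table::rbindlist(tiles)
  out[, partial := width < l]
  out[]
}

#' Read a two-column chromosome-sizes table
#'
#' @param path TSV with columns `chrom` and `length` (header optional).
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  x <- data.table::fread(path, header = "auto")
  if (ncol(x) < 2L) stop("chrom sizes table needs two columns", call. = FALSE)
  setNames(as.numeric(x[[2]]), as.character(x[[1]]))
}

#' Write genomic features to a BED6 file
#'
#' Converts internal 1-based closed coordinates to BED's 0-based half-open
#' convention. The score column carries whatever statistic `score_col` names
#' (divergence, exceedance probability, ...), documented in the header
#' comment.
#'
#' @param features A data frame with columns `chrom`, `start`, `end`
#'   (1-based closed) and optionally `name`, `strand`, and the score column.
#' @param path Output path.
#' @param score_col Name of the column to place in the BED score field
#'   (written as-is, not rescaled to 0-1000). `NULL` writes 0.
#' @param name_col Name column; `NULL` autonumbers.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(features, path, score_col = NULL,
                            name_col = NULL) {
  features <- as.data.frame(features)
  header <- sprintf("# BED6; score = %s; 0-based half-open",
                    score_col %||% "0")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(features) == 0L) return(invisible(path))
  if (!all(c("chrom", "start", "end") %in% names(features)))
    stop("features need chrom/start/end columns", call. = FALSE)
  name <- if (!is.null(name_col)) features[[name_col]]
          else sprintf("feature_%d", seq_len(nrow(features)))
  score <- if (!is.null(score_col)) features[[score_col]] else 0
  strand <- if ("strand" %in% names(features)) features$strand else "*"
  strand[!strand %in% c("+", "-")] <- "."
  bed <- data.frame(features$chrom, features$start - 1L, features$end,
                    name, score, strand)
  utils::write.table(bed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
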