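# Readers and writers for the two matrix dialects used repo-wide, plus
# bedGraph / BED track export. Both matrix dialects are plain text and
# lossless for counts, bins, weights, and mask. Coordinates are 0-based,
# half-open.

matrix_header_lines <- function(cm) {
  h <- c(sprintf("#resolution\t%.0f", cm$resolution),
         sprintf("#chrom\t%s\t%.0f", names(cm$genome$chrom_lengths),
                 unname(cm$genome$chrom_lengths)))
  if (any(!cm$mask))
    h <- c(h, sprintf("#masked\t%s", paste(which(!cm$mask), collapse = ",")))
  if (!is.null(cm$weights))
    h <- c(h, sprintf("#weights\t%s",
                      paste(format(cm$weights, digits = 17), collapse = ",")))
  h
}

parse_matrix_header <- function(lines) {
  kv <- strsplit(lines, "\t", fixed = TRUE)
  res <- NULL; chroms <- numeric(0); masked <- integer(0); weights <- NULL
  for (f in kv) {
    switch(f[[1]],
      "#resolution" = { res <- as.numeric(f[[2]]) },
      "#chrom" = { chroms[f[[2]]] <- as.numeric(f[[3]]) },
      "#masked" = { masked <- as.integer(strsplit(f[[2]], ",")[[1]]) },
      "#weights" = { weights <- suppressWarnings(
        as.numeric(strsplit(f[[2]], ",")[[1]])) },
      NULL)
  }
  if (is.null(res) || length(chroms) == 0)
    stop("malformed matrix file: missing #resolution or #chrom header")
  list(resolution = res, chroms = chroms, masked = masked, weights = weights)
}

#' Write a contact matrix to disk
#'
#' Two plain-text dialects: `"pairs"` is a sparse five-column bin-pair dump
#' (chrom1, start1, chrom2, start2, count; upper triangle only, zero cells
#' omitted); `"dense"` writes the full count matrix with a bin table.
#' Both carry genome, mask, and weight metadata in `#`-prefixed header lines
#' so that [read_matrix()] round-trips losslessly.
#'
#' @param cm a `contact_matrix`.
#' @param path output file path.
#' @param dialect `"pairs"` or `"dense"`.
#' @export
write_matrix <- function(cm, path, dialect = c("pairs", "dense")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(cm, "contact_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(matrix_header_lines(cm), con)
  if (dialect == "pairs") {
    ut <- which(upper.tri(cm$counts) & cm$counts != 0, arr.ind = TRUE)
    ord <- order(ut[, 1], ut[, 2])
    ut <- ut[ord, , drop = FALSE]
    df <- data.frame(chrom1 = cm$bins$chrom[ut[, 1]],
                     start1 = cm$bins$start[ut[, 1]],
                     chrom2 = cm$bins$chrom[ut[, 2]],
                     start2 = cm$bins$start[ut[, 2]],
                     count = cm$counts[ut])
    utils::write.table(format(df, scientific = FALSE, trim = TRUE), con,
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    writeLines(sprintf("#dense\t%d", nrow(cm$counts)), con)
    utils::write.table(format(cm$counts, digits = 17, scientific = FALSE,
                              trim = TRUE),
                       con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a contact matrix written by [write_matrix()]
#'
#' @param path file path.
#' @param dialect `"pairs"` or `"dense"`; `"auto"` sniffs the header.
#' @return a `contact_matrix`.
#' @export
read_matrix <- function(path, dialect = c("auto", "pairs", "dense")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  hdr <- startsWith(lines, "#")
  meta <- parse_matrix_header(lines[hdr])
  body <- lines[!hdr]
  if (dialect == "auto")
    dialect <- if (any(startsWith(lines, "#dense"))) "dense" else "pairs"
  genome <- genome_spec(meta$chroms, meta$resolution)
  bins <- genome_bins(genome)
  n <- nrow(bins)
  if (dialect == "dense") {
    m <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
    if (!all(dim(m) == c(n, n))) stop("dense matrix dimensions do not match bins")
    counts <- m
  } else {
    counts <- matrix(0, n, n)
    if (length(body) > 0) {
      rec <- utils::read.table(text = body, sep = "\t",
                               col.names = c("chrom1", "start1",
                                             "chrom2", "start2", "count"),
                               colClasses = c("character", "numeric",
                                              "character", "numeric", "numeric"))
      key <- function(ch, st) {
        if (any(st %% meta$resolution != 0 & st != 0))
          stop("record start not a multiple of the declared resolution")
        i <- match(paste(ch, st), paste(bins$chrom, bins$start))
        if (anyNA(i)) stop("record refers to a bin outside the declared genome")
        i
      }
      i <- key(rec$chrom1, rec$start1)
      j <- key(rec$chrom2, rec$start2)
      counts[cbind(i, j)] <- rec$count
      counts[cbind(j, i)] <- rec$count
    }
  }
  mask <- rep(TRUE, n)
  mask[meta$masked] <- FALSE
  cm <- contact_matrix(genome, counts, mask = mask)
  if (!is.null(meta$weights)) {
    cm$weights <- meta$weights
    w <- meta$weights
    w[is.na(w)] <- NA
    bal <- outer(w, w) * counts
    bal[!pair_valid(cm)] <- NA
    diag(bal) <- NA
    cm$balanced <- bal
  }
  cm
}

#' Write a per-bin track as bedGraph
#'
#' @param values numeric vector, one value per bin (NA rows are skipped).
#' @param bins bin table from [genome_bins()].
#' @param path output path.
#' @export
write_bedgraph <- function(values, bins, path) {
  stopifnot(length(values) == nrow(bins))
  keep <- !is.na(values)
  df <- data.frame(bins$chrom[keep], format(bins$start[keep], scientific = FALSE,
                                            trim = TRUE),
                   format(bins$end[keep], scientific = FALSE, trim = TRUE),
                   format(values[keep], digits = 10, scientific = FALSE,
                          trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph track onto a bin grid
#'
#' @param path bedGraph path (4 columns, no header).
#' @param genome a `genome_spec`; values are assigned to the bin containing
#'   each record's start.
#' @return numeric vector of per-bin values (NA where absent).
#' @export
read_bedgraph <- function(path, genome) {
  bins <- genome_bins(genome)
  df <- utils::read.table(path, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "numeric", "numeric",
                                         "numeric"))
  i <- match(paste(df$chrom, df$start), paste(bins$chrom, bins$start))
  out <- rep(NA_real_, nrow(bins))
  out[i[!is.na(i)]] <- df$value[!is.na(i)]
  out
}
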