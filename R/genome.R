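#' Define a toy or real binned genome
#'
#' A genome specification holds chromosome lengths and a single bin
#' resolution; every matrix, track, and interval in the package lives on the
#' dense bin grid it implies. Coordinates are 0-based, half-open throughout.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param resolution bin size in bp.
#' @return an object of class `genome_spec`.
#' @examples
#' g <- genome_spec(c(chr1 = 100e6, chr2 = 80e6), resolution = 1e6)
#' n_bins(g)
#' @export
genome_spec <- function(chrom_lengths, resolution) {
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == ""))
    stop("chrom_lengths must be a named vector")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0")
  if (length(resolution) != 1L || resolution <= 0)
    stop("resolution must be a single positive number")
  structure(
    list(chrom_lengths = chrom_lengths, resolution = as.numeric(resolution)),
    class = "genome_spec"
  )
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("genome_spec:", length(x$chrom_lengths), "chromosome(s),",
      format(x$resolution, big.mark = ","), "bp bins,",
      n_bins(x), "bins total\n")
  invisible(x)
}

#' Bin table of a genome
#'
#' @param genome a `genome_spec`.
#' @return data.frame with columns chrom, start, end, index (1-based global
#'   index, dense and sorted by chromosome then start).
#' @export
genome_bins <- function(genome) {
  stopifnot(inherits(genome, "genome_spec"))
  res <- genome$resolution
  pieces <- lapply(names(genome$chrom_lengths), function(ch) {
    len <- genome$chrom_lengths[[ch]]
    nb <- ceiling(len / res)
    start <- (seq_len(nb) - 1) * res
    data.frame(chrom = ch, start = start,
               end = pmin(start + res, len),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out$index <- seq_len(nrow(out))
  out
}

#' Total number of bins in a genome
#' @param genome a `genome_spec`.
#' @export
n_bins <- function(genome) {
  sum(ceiling(genome$chrom_lengths / genome$resolution))
}

# bins per chromosome, named
chrom_nbins <- function(genome) {
  ceiling(genome$chrom_lengths / genome$resolution)
}
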