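# Radial-positioning analysis of 3D genome-model bead ensembles: per-model
# centroid and distances, top-5% nuclear radius, QC filtering, the
# center / intermediate / peripheral classifier, and ensemble-averaged
# per-bin radial profiles with LAD overlay.

new_bead_ensemble <- function(models) {
  structure(list(models = models), class = "bead_ensemble")
}

#' @export
print.bead_ensemble <- function(x, ...) {
  nb <- vapply(x$models, function(m) nrow(m$beads), 0L)
  cat("bead_ensemble:", length(x$models), "model(s),",
      if (length(nb)) paste0(min(nb), "-", max(nb)) else 0, "beads each\n")
  invisible(x)
}

#' Read bead models from disk
#'
#' Two dialects: `"tsv"` — columns chrom, start, end, x, y, z, model (one
#' or many files); `"cmm"` — XML marker files (one model per file) whose
#' `<marker>` elements carry chrom/start/end/x/y/z attributes. Beads with a
#' missing or unparsable coordinate are kept but flagged invalid, never
#' dropped silently. A genomic bin duplicated within a model (beyond the
#' diploid pair handled downstream) is an error in the tsv dialect when
#' `check_duplicates` is TRUE.
#'
#' @param paths character vector of file paths.
#' @param dialect `"tsv"` or `"cmm"`.
#' @param check_duplicates error on duplicated bins within a model.
#' @return a `bead_ensemble`.
#' @export
read_bead_models <- function(paths, dialect = c("tsv", "cmm"),
                             check_duplicates = FALSE) {
  dialect <- match.arg(dialect)
  models <- list()
  if (dialect == "tsv") {
    df <- do.call(rbind, lapply(paths, function(p)
      utils::read.table(p, sep = "\t", header = TRUE,
                        colClasses = c("character", "numeric", "numeric",
                                       "numeric", "numeric", "numeric",
                                       "character"))))
    for (id in unique(df$model)) {
      b <- df[df$model == id, c("chrom", "start", "end", "x", "y", "z")]
      rownames(b) <- NULL
      b$valid <- is.finite(b$x) & is.finite(b$y) & is.finite(b$z)
      if (check_duplicates &&
          anyDuplicated(b[, c("chrom", "start")]) > 0)
        stop("duplicated genomic bin within model ", id)
      models[[length(models) + 1]] <- list(id = id, beads = b)
    }
  } else {
    for (p in paths) {
      doc <- xml2::read_xml(p)
      mk <- xml2::xml_find_all(doc, ".//marker")
      num <- function(attr) suppressWarnings(
        as.numeric(xml2::xml_attr(mk, attr)))
      b <- data.frame(chrom = xml2::xml_attr(mk, "chrom"),
                      start = num("start"), end = num("end"),
                      x = num("x"), y = num("y"), z = num("z"))
      b$valid <- is.finite(b$x) & is.finite(b$y) & is.finite(b$z)
      id <- xml2::xml_attr(xml2::xml_root(doc), "name")
      if (is.na(id)) id <- basename(p)
      models[[length(models) + 1]] <- list(id = id, beads = b)
    }
  }
  new_bead_ensemble(models)
}

#' Write bead models as TSV
#'
#' @param ensemble a `bead_ensemble`.
#' @param path output path (single TSV, `model` column distinguishes
#'   models).
#' @export
write_bead_models <- function(ensemble, path) {
  rows <- lapply(ensemble$models, function(m) {
    data.frame(m$beads[, c("chrom", "start", "end", "x", "y", "z")],
               model = m$id)
  })
  df <- do.call(rbind, rows)
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Centroid and per-bead distances of one model
#'
#' The nuclear center is the arithmetic mean of all valid bead coordinates;
#' each valid bead's distance is its Euclidean norm after centering.
#' Translation-invariant by construction.
#'
#' @param model one element of a `bead_ensemble` (list with `beads`).
#' @return list with `center` (length-3) and `distances` (per bead, NA for
#'   invalid beads).
#' @export
center_and_distances <- function(model) {
  b <- model$beads
  v <- b$valid
  if (!any(v)) stop("model has no valid beads")
  xyz <- as.matrix(b[, c("x", "y", "z")])
  center <- colMeans(xyz[v, , drop = FALSE])
  d <- rep(NA_real_, nrow(b))
  d[v] <- sqrt(rowSums((xyz[v, , drop = FALSE] -
                          matrix(center, sum(v), 3, byrow = TRUE))^2))
  list(center = center, distances = d)
}

#' Nuclear radius: mean distance of the farthest beads
#'
#' The radius is the mean of the `ceiling(top_fraction * n)` largest
#' distances (n = number of finite distances). Ties at the cut are resolved
#' by stable descending order, so exactly that many values enter the mean.
#'
#' @param distances numeric vector (NAs ignored).
#' @param top_fraction fraction of beads defining the boundary; default
#'   0.05.
#' @return radius scalar.
#' @export
nuclear_radius <- function(distances, top_fraction = 0.05) {
  d <- distances[is.finite(distances)]
  if (length(d) == 0) stop("no finite distances")
  k <- ceiling(top_fraction * length(d))
  mean(sort(d, decreasing = TRUE)[seq_len(k)])
}

#' QC-filter a bead ensemble
#'
#' Two rules, applied in order: (1) models with fewer than `min_beads`
#' valid beads are excluded; (2) among the survivors, models whose nuclear
#' radius deviates from the survivor mean by more than `sd_multiplier`
#' standard deviations are excluded. Every exclusion is logged with its
#' reason.
#'
#' @param ensemble a `bead_ensemble`.
#' @param min_beads minimum valid beads per model; default 20.
#' @param sd_multiplier radius outlier cut in SD units; default 3.
#' @param top_fraction passed to [nuclear_radius()].
#' @return list with `ensemble` (filtered), `exclusions`
#'   data.frame(model, reason, detail), and `radii` of the kept models.
#' @export
qc_filter <- function(ensemble, min_beads = 20, sd_multiplier = 3,
                      top_fraction = 0.05) {
  if (length(ensemble$models) == 0) stop("empty ensemble")
  ids <- vapply(ensemble$models, `[[`, "", "id")
  nvalid <- vapply(ensemble$models, function(m) sum(m$beads$valid), 0L)
  excl <- data.frame(model = character(0), reason = character(0),
                     detail = character(0))
  keep1 <- nvalid >= min_beads
  if (any(!keep1))
    excl <- rbind(excl, data.frame(
      model = ids[!keep1], reason = "min_beads",
      detail = sprintf("%d valid beads < %d", nvalid[!keep1], min_beads)))
  surv <- which(keep1)
  radii <- vapply(surv, function(i) {
    cd <- center_and_distances(ensemble$models[[i]])
    nuclear_radius(cd$distances, top_fraction)
  }, 0)
  if (length(surv) > 1 && stats::sd(radii) > 0) {
    dev <- abs(radii - mean(radii)) / stats::sd(radii)
    out <- dev > sd_multiplier
    if (any(out))
      excl <- rbind(excl, data.frame(
        model = ids[surv[out]], reason = "radius_outlier",
        detail = sprintf("radius %.3g at %.1f SD from mean", radii[out],
                         dev[out])))
    kept <- surv[!out]; radii <- radii[!out]
  } else kept <- surv
  if (length(kept) == 0) stop("all models excluded by QC")
  list(ensemble = new_bead_ensemble(ensemble$models[kept]),
       exclusions = excl, radii = radii)
}

#' Three-way radial classification of beads
#'
#' Relative distance r = distance / radius; class is `"center"` if
#' r < `center_cut`, `"peripheral"` if r > `peripheral_cut`, else
#' `"intermediate"` (values exactly at a cut are intermediate, matching the
#' strict inequalities of the center/peripheral definitions). r > 1 is
#' permitted and classed peripheral. Invariant under rigid rotation and
#' uniform scaling of the model.
#'
#' @param distances per-bead distances (NA = invalid bead).
#' @param radius nuclear radius (> 0).
#' @param center_cut,peripheral_cut relative-distance cuts; defaults 0.20
#'   and 0.80.
#' @return character vector of classes (NA for invalid beads).
#' @export
classify_beads <- function(distances, radius, center_cut = 0.20,
                           peripheral_cut = 0.80) {
  if (!is.finite(radius) || radius <= 0) stop("radius must be positive")
  r <- distances / radius
  ifelse(!is.finite(r), NA_character_,
         ifelse(r < center_cut, "center",
                ifelse(r > peripheral_cut, "peripheral", "intermediate")))
}

# per-model radial summary
radial_summary <- function(model, top_fraction = 0.05, radius = NULL, ...) {
  cd <- center_and_distances(model)
  if (is.null(radius)) radius <- nuclear_radius(cd$distances, top_fraction)
  cls <- classify_beads(cd$distances, radius, ...)
  list(center = cd$center, distances = cd$distances, radius = radius,
       relative = cd$distances / radius, class = cls)
}

#' Ensemble-averaged per-bin radial profile
#'
#' For every genomic bin: the mean relative distance across models (diploid
#' duplicate beads are first averaged within each model), the fraction of
#' models whose bin-average falls in each radial class, the number of
#' contributing models, and a LAD flag (>= `lad_min_overlap` of the bin
#' covered by a LAD interval). Relative distances are computed against each
#' model's own radius by default; set `ensemble_radius = TRUE` to normalize
#' every model by the mean radius of the ensemble instead.
#'
#' @param ensemble a QC-filtered `bead_ensemble`.
#' @param genome a `genome_spec` at the modeling resolution (typically
#'   1 Mb).
#' @param lad_intervals optional data.frame(chrom, start, end) of LADs.
#' @param ensemble_radius normalize by the ensemble-mean radius.
#' @param lad_min_overlap bin-overlap fraction for the LAD flag; default
#'   0.5.
#' @param ... passed to [classify_beads()].
#' @return a `radial_profile` data.frame(chrom, start, end, mean_rel_dist,
#'   frac_center, frac_intermediate, frac_peripheral, n_models, lad).
#' @export
ensemble_radial_profile <- function(ensemble, genome, lad_intervals = NULL,
                                    ensemble_radius = FALSE,
                                    lad_min_overlap = 0.5, ...) {
  bins <- genome_bins(genome)
  nbins <- nrow(bins)
  key <- paste(bins$chrom, bins$start)
  radii <- vapply(ensemble$models, function(m)
    nuclear_radius(center_and_distances(m)$distances), 0)
  shared_radius <- mean(radii)
  rel_sum <- rep(0, nbins); nmod <- rep(0L, nbins)
  cls_cnt <- matrix(0L, nbins, 3,
                    dimnames = list(NULL, c("center", "intermediate",
                                            "peripheral")))
  for (j in seq_along(ensemble$models)) {
    m <- ensemble$models[[j]]
    rs <- radial_summary(m, radius = if (ensemble_radius) shared_radius else
      radii[j], ...)
    bk <- paste(m$beads$chrom, m$beads$start)
    ok <- is.finite(rs$relative)
    per_bin <- tapply(rs$relative[ok], bk[ok], mean)
    at <- match(names(per_bin), key)
    hit <- !is.na(at)
    rel_sum[at[hit]] <- rel_sum[at[hit]] + per_bin[hit]
    nmod[at[hit]] <- nmod[at[hit]] + 1L
    bin_cls <- classify_beads(per_bin[hit] , 1, ...)
    for (cl in colnames(cls_cnt)) {
      w <- at[hit][bin_cls == cl]
      cls_cnt[w, cl] <- cls_cnt[w, cl] + 1L
    }
  }
  mean_rel <- ifelse(nmod > 0, rel_sum / nmod, NA_real_)
  fr <- cls_cnt / pmax(nmod, 1)
  fr[nmod == 0, ] <- NA_real_
  lad <- if (is.null(lad_intervals)) rep(FALSE, nbins) else
    bin_in_intervals(bins, lad_intervals, min_overlap = lad_min_overlap)
  out <- data.frame(bins[, c("chrom", "start", "end")],
                    mean_rel_dist = mean_rel,
                    frac_center = fr[, "center"],
                    frac_intermediate = fr[, "intermediate"],
                    frac_peripheral = fr[, "peripheral"],
                    n_models = nmod, lad = lad)
  class(out) <- c("radial_profile", "data.frame")
  out
}
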