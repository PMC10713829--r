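#' HDX configuration
#'
#' @param D_frac solvent deuterium fraction of the labeling reaction
#'   (0 < D_frac <= 1; default 0.8, i.e. 5 uL protiated sample diluted into
#'   20 uL deuterated buffer).
#' @param correction_variant `"span"` (default): uptake relative to the
#'   all-H/all-D reference span `(m_t - m0)/(m100 - m0)`; `"d-scaled"`:
#'   denominator additionally scaled by `D_frac`, the reading of the
#'   printed back-exchange formula under which exchange saturated at the
#'   solvent fraction reports 100%. The variant used is recorded in every
#'   output.
#' @param timepoints labeling times in seconds (default 0, 20, 60, 180,
#'   600).
#' @return object of class `HdxConfig`.
#' @export
hdx_config <- function(D_frac = 0.8,
                       correction_variant = c("span", "d-scaled"),
                       timepoints = c(0, 20, 60, 180, 600)) {
  if (!(D_frac > 0 && D_frac <= 1)) stop("D_frac must be in (0, 1]")
  structure(list(D_frac = D_frac,
                 correction_variant = match.arg(correction_variant),
                 timepoints = timepoints),
            class = "HdxConfig")
}

#' Deuterium fraction of a labeling reaction from mixing volumes
#'
#' @param vol_sample protiated sample volume (e.g. 5 uL).
#' @param vol_buffer deuterated buffer volume (e.g. 20 uL).
#' @return `vol_buffer / (vol_sample + vol_buffer)`.
#' @export
hdx_dilution_fraction <- function(vol_sample, vol_buffer) {
  stopifnot(vol_sample > 0, vol_buffer > 0)
  vol_buffer / (vol_sample + vol_buffer)
}

#' Back-exchange-corrected percent deuterium uptake
#'
#' `span` variant: `(m_t - m0)/(m100 - m0) * 100`; `d-scaled` variant:
#' `(m_t - m0)/(D_frac * (m100 - m0)) * 100`. `m0` is the all-H reference
#' centroid, `m100` the all-D reference centroid; both references already
#' carry the experimental back-exchange, so the span form is the default.
#' Affine-invariant: adding a constant to all three masses leaves the
#' result unchanged.
#'
#' @param m_t centroid mass at the timepoint (Da); vectorized.
#' @param m0,m100 all-H and all-D reference centroids (Da).
#' @param cfg `HdxConfig`.
#' @return percent uptake.
#' @export
percent_uptake <- function(m_t, m0, m100, cfg = hdx_config()) {
  span <- m100 - m0
  if (span <= 0) stop("m100 must exceed m0")
  denom <- switch(cfg$correction_variant,
                  "span" = span,
                  "d-scaled" = cfg$D_frac * span)
  (m_t - m0) / denom * 100
}

#' A peptic-fragment centroid-mass series
#'
#' @param protein protein label.
#' @param start,end inclusive 1-based residue span in construct numbering.
#' @param sequence amino-acid sequence (length `end - start + 1`).
#' @param m0,m100 all-H / all-D reference centroids (Da), `m100 >= m0`.
#' @param observations data.frame with `time_s`, `replicate`, `m_t` (Da).
#' @return object of class `HdxFragmentSeries`.
#' @export
hdx_fragment <- function(protein, start, end, sequence, m0, m100,
                         observations) {
  if (start > end) stop("start must be <= end")
  if (nchar(sequence) != end - start + 1L)
    stop("sequence length does not match span ", start, "-", end)
  if (m100 < m0) stop("m100 must be >= m0")
  stopifnot(all(c("time_s", "replicate", "m_t") %in% names(observations)))
  structure(list(protein = protein, start = as.integer(start),
                 end = as.integer(end), sequence = sequence,
                 m0 = m0, m100 = m100,
                 observations = as.data.frame(observations)),
            class = "HdxFragmentSeries")
}

#' Per-fragment uptake curves (mean and SD over replicates)
#'
#' Corrected uptake is computed per observation and summarized per time
#' with the sample SD (n-1). Time 0 is forced to 0% by definition.
#'
#' @param frags list of `HdxFragmentSeries`.
#' @param cfg `HdxConfig`.
#' @return data.frame (`protein`, `start`, `end`, `time_s`, `mean_uptake`,
#'   `sd_uptake`, `n`, `variant`), times sorted within fragment.
#' @export
build_uptake_curves <- function(frags, cfg = hdx_config()) {
  if (inherits(frags, "HdxFragmentSeries")) frags <- list(frags)
  rows <- lapply(frags, function(fr) {
    obs <- fr$observations
    u <- percent_uptake(obs$m_t, fr$m0, fr$m100, cfg)
    u[obs$time_s == 0] <- 0
    agg_mean <- tapply(u, obs$time_s, mean)
    agg_sd <- tapply(u, obs$time_s, function(v)
      if (length(v) > 1L) stats::sd(v) else 0)
    agg_n <- tapply(u, obs$time_s, length)
    times <- as.numeric(names(agg_mean))
    o <- order(times)
    data.frame(protein = fr$protein, start = fr$start, end = fr$end,
               time_s = times[o], mean_uptake = as.numeric(agg_mean)[o],
               sd_uptake = as.numeric(agg_sd)[o], n = as.integer(agg_n)[o],
               variant = cfg$correction_variant, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Residue-resolved uptake map from overlapping fragments
#'
#' Each residue's value is the mean of the percent uptake of every fragment
#' whose span covers it (uniform redistribution along the fragment);
#' `weighting = "length"` weights each covering fragment by the inverse of
#' its length instead. Uncovered residues are flagged, never interpolated.
#' Optionally the first residue of each fragment and prolines (fast
#' back-exchanging amides) can be excluded from coverage.
#'
#' @param curves output of [build_uptake_curves()] (or a data.frame with
#'   `start`, `end`, `time_s`, `mean_uptake`).
#' @param protein_length construct length in residues.
#' @param time_s timepoint to resolve (default 600).
#' @param weighting `"uniform"` (default) or `"length"`.
#' @param exclude_fast drop the first residue of each fragment from
#'   coverage (default FALSE).
#' @param proline_positions optional residue numbers excluded from coverage
#'   when `exclude_fast` is set.
#' @return object of class `ResidueUptakeMap`: data.frame (`resno`,
#'   `uptake`, `coverage`, `covered`).
#' @export
residue_resolve <- function(curves, protein_length, time_s = 600,
                            weighting = c("uniform", "length"),
                            exclude_fast = FALSE,
                            proline_positions = integer()) {
  weighting <- match.arg(weighting)
  at_t <- curves[curves$time_s == time_s, , drop = FALSE]
  if (nrow(at_t) == 0L) stop("no fragments at time ", time_s, " s")
  if (any(at_t$start < 1L | at_t$end > protein_length))
    stop("fragment span outside protein (length ", protein_length, ")")
  num <- numeric(protein_length)
  wsum <- numeric(protein_length)
  cover <- integer(protein_length)
  for (i in seq_len(nrow(at_t))) {
    res <- seq(at_t$start[i], at_t$end[i])
    if (exclude_fast) res <- setdiff(res[-1L], proline_positions)
    if (length(res) == 0L) next
    w <- if (weighting == "uniform") 1 else 1 / (at_t$end[i] - at_t$start[i] + 1L)
    num[res] <- num[res] + w * at_t$mean_uptake[i]
    wsum[res] <- wsum[res] + w
    cover[res] <- cover[res] + 1L
  }
  uptake <- ifelse(wsum > 0, num / wsum, NA_real_)
  structure(data.frame(resno = seq_len(protein_length), uptake = uptake,
                       coverage = cover, covered = cover > 0L),
            class = c("ResidueUptakeMap", "data.frame"))
}

#' Paint per-residue values into a model's B-factor column
#'
#' Attaches a per-atom value vector (e.g. resolved percent uptake) to a
#' model so [write_pdb()] emits it in the B-factor field, the conventional
#' channel for coloring structures by a residue-level quantity. Residues
#' absent from the map receive `missing_value`.
#'
#' @param m `StructureModel`.
#' @param map `ResidueUptakeMap` (or any data.frame with `resno` and a
#'   value column).
#' @param chain chain to paint (others get `missing_value`).
#' @param column value column name (default `"uptake"`).
#' @param missing_value filler for unmapped residues (default 0).
#' @return the model with a `bfactor` vector attached.
#' @export
paint_bfactor <- function(m, map, chain, column = "uptake",
                          missing_value = 0) {
  vals <- map[[column]][match(m$atoms$resno, map$resno)]
  vals[m$atoms$chain != chain | is.na(vals)] <- missing_value
  m$bfactor <- vals
  m
}

#' Read HDX fragment tables from CSV
#'
#' Expected columns: `protein`, `start`, `end`, `sequence`, `replicate`,
#' `time_s`, `centroid_mass`. Reference rows carry `time_s` of `allH`
#' (m0) and `allD` (m100) (replicates averaged).
#'
#' @param path CSV file.
#' @return list of `HdxFragmentSeries`.
#' @export
read_hdx_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("protein", "start", "end", "sequence", "replicate", "time_s",
            "centroid_mass")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L)
    stop("HDX table missing columns: ", paste(miss, collapse = ", "))
  key <- paste(tab$protein, tab$start, tab$end, sep = "|")
  lapply(unique(key), function(k) {
    d <- tab[key == k, ]
    is_h <- d$time_s == "allH"
    is_d <- d$time_s == "allD"
    if (!any(is_h) || !any(is_d))
      stop("fragment ", k, " lacks allH/allD reference rows")
    obs <- d[!is_h & !is_d, ]
    hdx_fragment(d$protein[1L], d$start[1L], d$end[1L], d$sequence[1L],
                 m0 = mean(d$centroid_mass[is_h]),
                 m100 = mean(d$centroid_mass[is_d]),
                 observations = data.frame(
                   time_s = as.numeric(obs$time_s),
                   replicate = obs$replicate,
                   m_t = obs$centroid_mass))
  })
}

#' Write an HDX fragment list to CSV (round-trips [read_hdx_table()])
#' @param frags list of `HdxFragmentSeries`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_hdx_table <- function(frags, path) {
  if (inherits(frags, "HdxFragmentSeries")) frags <- list(frags)
  rows <- lapply(frags, function(fr) {
    obs <- fr$observations
    rbind(
      data.frame(protein = fr$protein, start = fr$start, end = fr$end,
                 sequence = fr$sequence, replicate = 1L, time_s = "allH",
                 centroid_mass = fr$m0, stringsAsFactors = FALSE),
      data.frame(protein = fr$protein, start = fr$start, end = fr$end,
                 sequence = fr$sequence, replicate = 1L, time_s = "allD",
                 centroid_mass = fr$m100, stringsAsFactors = FALSE),
      data.frame(protein = fr$protein, start = fr$start, end = fr$end,
                 sequence = fr$sequence, replicate = obs$replicate,
                 time_s = as.character(obs$time_s),
                 centroid_mass = obs$m_t, stringsAsFactors = FALSE)
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
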