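#' Kyte-Doolittle hydropathy scale
#'
#' @return Named numeric vector of residue hydropathy values for the 20
#'   standard amino acids.
#' @export
kd_scale <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

#' Windowed hydropathy profile of a protein
#'
#' Centred moving average of Kyte-Doolittle residue hydropathy, the
#' classic transparent proxy for transmembrane propensity (a 19-residue
#' window with values above ~1.6 flags candidate TM helices). Windows are
#' truncated at the termini rather than padded. Unknown residues
#' (including `*` and `X`) contribute 0 with a warning.
#'
#' @param protein A single protein string, at least `window` residues.
#' @param window Odd window width >= 5 (default 19).
#' @param scale Residue scale, as from [kd_scale()].
#' @return A tibble `residue` (1-based position), `aa`, `hydropathy`.
#' @export
hydropathy_profile <- function(protein, window = 19, scale = kd_scale()) {
  if (!is_scalar_string(protein)) abort("`protein` must be a single string")
  if (window < 5 || window %% 2 == 0) abort("`window` must be odd and >= 5")
  aa <- chars(toupper(protein))
  if (length(aa) < window) {
    abort(sprintf("protein length %d is shorter than the window (%d)",
                  length(aa), window))
  }
  vals <- unname(scale[aa])
  if (anyNA(vals)) {
    warn(sprintf("%d residue(s) outside the scale treated as 0 (%s)",
                 sum(is.na(vals)), paste(unique(aa[is.na(vals)]), collapse = ", ")))
    vals[is.na(vals)] <- 0
  }
  h <- (window - 1) / 2
  n <- length(vals)
  cs <- cumsum(c(0, vals))
  lo <- pmax(1, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  tibble(residue = seq_len(n), aa = aa,
         hydropathy = (cs[hi + 1] - cs[lo]) / (hi - lo + 1))
}

#' Call transmembrane segments from a hydropathy profile
#'
#' Maximal runs of windowed hydropathy above `threshold` of at least
#' `min_len` residues become segments. This is a deliberately simple
#' hydropathy heuristic for comparing edited vs unedited protein forms —
#' it does not model signal peptides or helix topology.
#'
#' @param profile Tibble from [hydropathy_profile()] (needs `residue`,
#'   `hydropathy`), or a bare numeric profile.
#' @param threshold Hydropathy cutoff (default 1.6).
#' @param min_len Minimum run length in residues (default 15).
#' @param protein_id Optional label carried on the result.
#' @return An object of class `cp_tm_map`: list with `protein_id`,
#'   `length` (residues), `segments` (tibble `start`, `end`, 1-based
#'   inclusive, non-overlapping, sorted), `profile`, `threshold`,
#'   `min_len`.
#' @export
call_tm_segments <- function(profile, threshold = 1.6, min_len = 15,
                             protein_id = NA_character_) {
  if (is.numeric(profile)) {
    profile <- tibble(residue = seq_along(profile),
                      aa = NA_character_, hydropathy = as.numeric(profile))
  }
  stopifnot(all(c("residue", "hydropathy") %in% names(profile)))
  above <- profile$hydropathy > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  structure(list(
    protein_id = protein_id,
    length = nrow(profile),
    segments = tibble(start = as.integer(starts[keep]), end = as.integer(ends[keep])),
    profile = profile,
    threshold = threshold,
    min_len = min_len
  ), class = "cp_tm_map")
}

#' @export
print.cp_tm_map <- function(x, ...) {
  cat(sprintf("TM map%s: %d residue(s), %d segment(s) (hydropathy > %s, run >= %d)\n",
              if (is.na(x$protein_id)) "" else paste0(" for ", x$protein_id),
              x$length, nrow(x$segments), format(x$threshold), x$min_len))
  if (nrow(x$segments)) print(as.data.frame(x$segments), row.names = FALSE)
  invisible(x)
}

#' Compare transmembrane maps before and after editing
#'
#' Interval diff of two TM maps on the same protein length. Segments of
#' `after` with no overlap in `before` are `gained`; overlapping segments
#' covering residues that `before` does not are `extended`. Symmetrically,
#' `before` segments absent from `after` are `lost` and overlapping but
#' reduced ones `shrunk`. Segments covered identically are not reported.
#'
#' @param before,after `cp_tm_map` objects of equal protein length.
#' @return A tibble `status` (gained/extended/lost/shrunk), `start`,
#'   `end`, `length_res` (segment length), empty when the maps cover the
#'   same residues segment-for-segment.
#' @export
compare_tm_maps <- function(before, after) {
  stopifnot(inherits(before, "cp_tm_map"), inherits(after, "cp_tm_map"))
  if (before$length != after$length) {
    abort(sprintf("protein lengths differ (%d vs %d)", before$length, after$length))
  }
  cover <- function(map) {
    v <- logical(map$length)
    for (i in seq_len(nrow(map$segments))) {
      v[map$segments$start[i]:map$segments$end[i]] <- TRUE
    }
    v
  }
  cov_b <- cover(before)
  cov_a <- cover(after)
  diff_one <- function(segs, own_cov, other_cov, none_status, more_status) {
    if (!nrow(segs)) return(NULL)
    rows <- pmap(segs, function(start, end) {
      idx <- start:end
      if (!any(other_cov[idx])) {
        tibble(status = none_status, start = start, end = end,
               length_res = length(idx))
      } else if (any(own_cov[idx] & !other_cov[idx])) {
        tibble(status = more_status, start = start, end = end,
               length_res = length(idx))
      } else {
        NULL
      }
    })
    rows <- purrr::compact(rows)
    if (!length(rows)) return(NULL)
    list_rbind(rows)
  }
  out <- bind_rows(
    diff_one(after$segments, cov_a, cov_b, "gained", "extended"),
    diff_one(before$segments, cov_b, cov_a, "lost", "shrunk")
  )
  if (!nrow(out)) {
    out <- tibble(status = character(), start = integer(), end = integer(),
                  length_res = integer())
  }
  out
}
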