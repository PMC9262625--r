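## Assignment transfer, chemical-shift-perturbation scoring, split-peak
## detection and conformer classification on methyl HMQC peak lists.

.peaklist_cols <- c("assignment", "aa", "methyl_id", "dH_ppm", "dC_ppm",
                    "intensity")

.check_peaklist <- function(x, what = "peak list") {
  miss <- setdiff(.peaklist_cols, names(x))
  if (length(miss) > 0)
    stop(what, " lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(x$intensity)) || any(x$intensity <= 0))
    stop(what, ": intensities must be > 0", call. = FALSE)
  if (any(x$dH_ppm < -2 | x$dH_ppm > 3) || any(x$dC_ppm < 5 | x$dC_ppm > 30))
    warning(what, ": peaks outside the methyl region ",
            "(dH in [-2, 3], dC in [5, 30] ppm)", call. = FALSE)
  invisible(x)
}

#' Read / write a tab-separated methyl peak list
#'
#' Columns: `assignment` (empty for unassigned), `aa`, `methyl_id`,
#' `dH_ppm`, `dC_ppm`, `intensity`.  Lines starting with `#` are ignored.
#'
#' @param path File path.
#' @param state_label Sample-state label attached to the returned list.
#' @return `read_peaklist()`: a peak-list data frame.
#' @export
read_peaklist <- function(path, state_label = basename(path)) {
  x <- read.delim(path, header = TRUE, comment.char = "#",
                  stringsAsFactors = FALSE, na.strings = NULL)
  x$assignment <- as.character(x$assignment)
  x$assignment[is.na(x$assignment)] <- ""
  .check_peaklist(x)
  attr(x, "state_label") <- state_label
  x
}

#' @rdname read_peaklist
#' @param peaks Peak-list data frame to write.
#' @export
write_peaklist <- function(peaks, path) {
  .check_peaklist(peaks)
  out <- peaks[.peaklist_cols]
  for (col in c("dH_ppm", "dC_ppm", "intensity"))
    out[[col]] <- sprintf("%.17g", out[[col]])   # lossless round trip
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Combined 1H/13C chemical-shift perturbation
#'
#' \eqn{\Delta\delta = \sqrt{\Delta\delta_H^2 + (w_C \Delta\delta_C)^2}}
#' with the conventional carbon weight of 0.25.
#'
#' @param dH,dC Shift differences, ppm (vectorised).
#' @param w_c Carbon weight (default 0.25).
#' @return Combined shift perturbation, ppm.
#' @examples
#' combined_csp(0.03, 0.2)
#' @export
combined_csp <- function(dH, dC, w_c = 0.25) {
  stopifnot(all(is.finite(dH)), all(is.finite(dC)))
  sqrt(dH^2 + (w_c * dC)^2)
}

#' Transfer assignments from a reference to a target peak list
#'
#' Each target peak is matched to the reference assignment minimising the
#' scaled elliptical distance
#' \eqn{d = \sqrt{(\Delta\delta_H/tol_H)^2 + (\Delta\delta_C/tol_C)^2}},
#' accepting matches with \eqn{d \le 1}.  Matching is greedy in order of
#' increasing distance; target peaks are consumed once, but one reference
#' assignment may acquire several target peaks — a split, the signature of
#' multiple bound conformations.  This mirrors the manual practice of
#' inferring the identity of shifted cross peaks from their proximity to
#' the free-protein peak.
#'
#' @param reference Fully assigned peak list (data frame).
#' @param target Peak list to annotate (assignments ignored).
#' @param tol_h,tol_c Matching tolerances, ppm (defaults 0.05 and 0.3,
#'   typical methyl linewidths).
#' @param w_c Carbon weight for the reported combined CSP.
#' @return An object of class `match_report`: `matches` (one row per
#'   matched target peak: assignment, component index, dH, dC, distance,
#'   combined CSP, intensity and intensity fraction within the
#'   assignment), `by_assignment` (per-assignment summary with `n_components`,
#'   `split` flag, max CSP, smallest component intensity ratio) and
#'   `unmatched_target` (target rows matched to nothing).
#' @export
transfer_assignments <- function(reference, target, tol_h = 0.05,
                                 tol_c = 0.3, w_c = 0.25) {
  .check_peaklist(reference, "reference")
  .check_peaklist(target, "target")
  if (nrow(reference) == 0L || nrow(target) == 0L)
    stop("reference and target peak lists must be non-empty", call. = FALSE)
  if (any(reference$assignment == ""))
    stop("reference peak list must be fully assigned", call. = FALSE)

  ## all candidate pairs with d <= 1
  cand <- NULL
  if (tol_h > 0 && tol_c > 0) {
    dh <- outer(target$dH_ppm, reference$dH_ppm, "-") / tol_h
    dc <- outer(target$dC_ppm, reference$dC_ppm, "-") / tol_c
    d <- sqrt(dh^2 + dc^2)
    hit <- which(d <= 1, arr.ind = TRUE)
    if (nrow(hit) > 0)
      cand <- data.frame(tgt = hit[, 1], ref = hit[, 2],
                         d = d[hit])
  } else {
    same <- outer(target$dH_ppm, reference$dH_ppm, "==") &
      outer(target$dC_ppm, reference$dC_ppm, "==")
    hit <- which(same, arr.ind = TRUE)
    if (nrow(hit) > 0)
      cand <- data.frame(tgt = hit[, 1], ref = hit[, 2], d = 0)
  }

  matches <- NULL
  if (!is.null(cand)) {
    cand <- cand[order(cand$d), , drop = FALSE]
    used_tgt <- rep(FALSE, nrow(target))
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (!used_tgt[cand$tgt[i]]) {
        keep[i] <- TRUE
        used_tgt[cand$tgt[i]] <- TRUE
      }
    }
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) > 0) {
      matches <- data.frame(
        assignment = reference$assignment[cand$ref],
        dH_ppm = target$dH_ppm[cand$tgt] - reference$dH_ppm[cand$ref],
        dC_ppm = target$dC_ppm[cand$tgt] - reference$dC_ppm[cand$ref],
        distance = cand$d,
        intensity = target$intensity[cand$tgt],
        stringsAsFactors = FALSE)
      matches$csp <- combined_csp(matches$dH_ppm, matches$dC_ppm, w_c)
      matches <- matches[order(matches$assignment, matches$distance), ,
                         drop = FALSE]
      matches$component <- as.integer(
        stats::ave(seq_len(nrow(matches)), matches$assignment,
                   FUN = seq_along))
      tot <- tapply(matches$intensity, matches$assignment, sum)
      matches$intensity_fraction <-
        matches$intensity / as.numeric(tot[matches$assignment])
      rownames(matches) <- NULL
      used <- cand$tgt
    } else used <- integer()
  } else used <- integer()

  if (is.null(matches))
    matches <- data.frame(assignment = character(), dH_ppm = numeric(),
                          dC_ppm = numeric(), distance = numeric(),
                          intensity = numeric(), csp = numeric(),
                          component = integer(),
                          intensity_fraction = numeric())

  n_comp <- if (nrow(matches)) table(matches$assignment) else
    table(character())
  by_asn <- data.frame(assignment = reference$assignment,
                       stringsAsFactors = FALSE)
  by_asn$n_components <- as.integer(n_comp[by_asn$assignment])
  by_asn$n_components[is.na(by_asn$n_components)] <- 0L
  by_asn$split <- by_asn$n_components >= 2L
  by_asn$csp_max <- vapply(by_asn$assignment, function(a) {
    v <- matches$csp[matches$assignment == a]
    if (length(v)) max(v) else NA_real_
  }, 0)
  by_asn$intensity_ratio <- vapply(by_asn$assignment, function(a) {
    v <- matches$intensity_fraction[matches$assignment == a]
    if (length(v) >= 2L) min(v) / max(v) else NA_real_
  }, 0)

  unmatched <- target[setdiff(seq_len(nrow(target)), used), , drop = FALSE]
  structure(list(matches = matches, by_assignment = by_asn,
                 unmatched_target = unmatched,
                 tol_h = tol_h, tol_c = tol_c),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  n_split <- sum(x$by_assignment$split)
  cat(sprintf("<match_report> %d/%d assignments matched, %d split, %d target peaks unmatched\n",
              sum(x$by_assignment$n_components > 0),
              nrow(x$by_assignment), n_split, nrow(x$unmatched_target)))
  invisible(x)
}

#' Fractional conformer populations from split-peak intensities
#'
#' Normalises the component intensities of a split cross peak to unit sum.
#' Intensity is proportional to population only when the components relax
#' comparably; the returned vector carries a `caveat` attribute stating
#' this assumption.
#'
#' @param intensities Numeric vector of component intensities (>= 2).
#' @return Fractions summing to 1.
#' @examples
#' conformer_populations(c(3, 1))
#' @export
conformer_populations <- function(intensities) {
  if (length(intensities) < 2L)
    stop("need at least two split components", call. = FALSE)
  if (any(!is.finite(intensities)) || any(intensities <= 0))
    stop("intensities must be positive", call. = FALSE)
  out <- intensities / sum(intensities)
  attr(out, "caveat") <-
    "intensity fractions equal populations only under equal relaxation"
  out
}

#' Classify a bound state as single or multiple conformations
#'
#' A complex is called `multiple_conformations` when at least `min_split`
#' assignments carry split flags in the match report, else
#' `single_conformation`.  With no matches at all the verdict is
#' `single_conformation` with a `low_confidence` attribute.
#'
#' @param report A `match_report` from [transfer_assignments()].
#' @param min_split Minimum number of split assignments (default 2).
#' @return `"single_conformation"` or `"multiple_conformations"`, with
#'   attribute `n_split`.
#' @export
classify_complex <- function(report, min_split = 2L) {
  stopifnot(inherits(report, "match_report"))
  n_split <- sum(report$by_assignment$split)
  out <- if (n_split >= min_split) "multiple_conformations" else
    "single_conformation"
  attr(out, "n_split") <- n_split
  if (sum(report$by_assignment$n_components) == 0L)
    attr(out, "low_confidence") <- TRUE
  out
}
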