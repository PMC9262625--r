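## Construction of R2,eff profiles from constant-time peak intensities,
## duplicate-based error estimation, Rex screening, and the tab-separated
## interchange formats.
##
## The working currency for a dataset is a long data frame with columns
##   residue_id, aa, methyl_id, field_label, nu_cpmg_hz, r2eff_s, sigma_s
## where duplicate measurements appear as repeated nu rows.  A "profile" is
## the subset of rows for one methyl at one field.

.methyl_key <- function(residue_id, methyl_id) paste0(residue_id, ".", methyl_id)

.dispersion_cols <- c("residue_id", "aa", "methyl_id", "field_label",
                      "nu_cpmg_hz", "r2eff_s", "sigma_s")

.check_dispersion_df <- function(x) {
  miss <- setdiff(.dispersion_cols, names(x))
  if (length(miss) > 0)
    stop("dispersion table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(x)
}

#' Effective relaxation rates from constant-time peak intensities
#'
#' For one methyl group at one field, converts peak intensities measured in
#' a constant-time CPMG experiment into effective relaxation rates,
#' \eqn{R_{2,eff}(\nu) = -\ln(I(\nu)/I_{ref})/T_{relax}}.  Replicate
#' intensities at one frequency are averaged; replicate pairs (including a
#' duplicated reference) are retained in the `pairs` attribute for error
#' estimation by [estimate_sigma_from_duplicates()].
#'
#' @param records Data frame for one methyl and one field with columns
#'   `nu_cpmg_hz` (`NA` for reference rows) and `intensity` (> 0).
#'   Additional identifying columns (`residue_id`, `aa`, `methyl_id`,
#'   `field_label`) are carried through when present.
#' @param t_relax Constant relaxation period, s.
#' @return A dispersion-profile data frame (one row per unique frequency)
#'   with columns `nu_cpmg_hz` and `r2eff_s`, plus identifying columns, and
#'   an attribute `pairs`: a data frame of duplicate pairs in R2,eff units
#'   (`nu_cpmg_hz` is `NA` for the reference pair).
#' @examples
#' rec <- data.frame(nu_cpmg_hz = c(NA, 200, 1000),
#'                   intensity = c(1, 0.5, 0.8))
#' r2eff_from_intensities(rec, t_relax = 0.02)
#' @export
r2eff_from_intensities <- function(records, t_relax) {
  stopifnot(is.data.frame(records), all(c("nu_cpmg_hz", "intensity") %in%
                                          names(records)))
  if (any(!is.finite(records$intensity)) || any(records$intensity <= 0))
    stop("all intensities must be finite and > 0", call. = FALSE)
  is_ref <- is.na(records$nu_cpmg_hz)
  if (!any(is_ref))
    stop("records must contain a reference row (nu_cpmg_hz = NA)",
         call. = FALSE)
  i_ref <- mean(records$intensity[is_ref])
  meas <- records[!is_ref, , drop = FALSE]
  if (nrow(meas) == 0L)
    stop("records contain no CPMG measurements", call. = FALSE)
  r2 <- -log(meas$intensity / i_ref) / t_relax
  if (any(r2 < 0))
    warning("intensity above reference gives negative R2,eff (kept)",
            call. = FALSE)

  nu_levels <- sort(unique(meas$nu_cpmg_hz))
  r2_mean <- vapply(nu_levels,
                    function(v) mean(r2[meas$nu_cpmg_hz == v]), 0)
  prof <- data.frame(nu_cpmg_hz = nu_levels, r2eff_s = r2_mean)
  for (col in c("residue_id", "aa", "methyl_id", "field_label"))
    if (col %in% names(records)) prof[[col]] <- records[[col]][1L]

  ## duplicate pairs in R2,eff units; reference pair relative to mean ref
  pairs <- list()
  ref_int <- records$intensity[is_ref]
  if (length(ref_int) >= 2L) {
    rr <- -log(ref_int[1:2] / i_ref) / t_relax
    pairs[[length(pairs) + 1L]] <-
      data.frame(nu_cpmg_hz = NA_real_, r2eff_1 = rr[1], r2eff_2 = rr[2])
  }
  for (v in nu_levels) {
    rv <- r2[meas$nu_cpmg_hz == v]
    if (length(rv) >= 2L)
      pairs[[length(pairs) + 1L]] <-
        data.frame(nu_cpmg_hz = v, r2eff_1 = rv[1], r2eff_2 = rv[2])
  }
  attr(prof, "pairs") <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(nu_cpmg_hz = numeric(), r2eff_1 = numeric(),
               r2eff_2 = numeric())
  prof
}

#' Pooled point error from duplicate measurements
#'
#' Estimates the per-point uncertainty of R2,eff values from duplicate
#' measurements, pooled per field: each pair contributes its squared
#' half-difference (for a pair differing by \eqn{2\delta} the implied
#' per-measurement standard deviation is \eqn{\delta\sqrt{2}}), and the
#' pooled estimate is the root of the mean of \eqn{(x_1-x_2)^2/2} over all
#' pairs of that field.  A floor of `sigma_min` is applied.  Duplicates are
#' sparse in practice (reference plus two schedule positions), so one sigma
#' per field, applied uniformly to all of that field's points, is the most
#' the data support.
#'
#' @param dataset Long dispersion data frame (see
#'   [read_dispersion_table()]); duplicates are repeated
#'   (residue, methyl, field, nu) rows.
#' @param sigma_min Floor on the estimate, s^-1 (default 0.1).
#' @return Named numeric vector: one sigma (s^-1) per field label.
#' @export
estimate_sigma_from_duplicates <- function(dataset, sigma_min = 0.1) {
  .check_dispersion_df(dataset)
  out <- c()
  for (fl in unique(dataset$field_label)) {
    d <- dataset[dataset$field_label == fl, , drop = FALSE]
    key <- paste(d$residue_id, d$methyl_id, d$nu_cpmg_hz)
    halves2 <- c()
    for (k in unique(key[duplicated(key)])) {
      v <- d$r2eff_s[key == k]
      halves2 <- c(halves2, diff(v[1:2])^2 / 2)
    }
    if (length(halves2) == 0L) next
    out[fl] <- max(sigma_min, sqrt(mean(halves2)))
  }
  if (length(out) == 0L)
    stop("no duplicate measurements found in any field; ",
         "supply point uncertainties explicitly", call. = FALSE)
  out
}

#' Collapse duplicate rows of a dispersion dataset
#'
#' Averages repeated (residue, methyl, field, nu) measurements into single
#' points, e.g. before fitting.
#'
#' @param dataset Long dispersion data frame.
#' @return Data frame with one row per unique point.
#' @export
collapse_duplicates <- function(dataset) {
  .check_dispersion_df(dataset)
  key <- paste(dataset$residue_id, dataset$methyl_id, dataset$field_label,
               dataset$nu_cpmg_hz, sep = "\r")
  agg <- tapply(dataset$r2eff_s, key, mean)
  first <- dataset[!duplicated(key), , drop = FALSE]
  first$r2eff_s <- as.numeric(agg[paste(first$residue_id, first$methyl_id,
                                        first$field_label, first$nu_cpmg_hz,
                                        sep = "\r")])
  ord <- order(first$residue_id, first$methyl_id, first$field_label,
               first$nu_cpmg_hz)
  rownames(first) <- NULL
  first[ord, , drop = FALSE]
}

#' Observed exchange contribution of one profile
#'
#' The vertical displacement of the dispersion curve, read as the mean
#' R2,eff of the two lowest refocusing frequencies minus the mean of the two
#' highest.  Two-point means at each end damp single-point noise.
#'
#' @param profile Data frame with columns `nu_cpmg_hz` and `r2eff_s` for
#'   one methyl at one field (>= 2 points).
#' @return Observed \eqn{R_{ex}}, s^-1.
#' @export
rex_observed <- function(profile) {
  stopifnot(is.data.frame(profile),
            all(c("nu_cpmg_hz", "r2eff_s") %in% names(profile)))
  if (nrow(profile) < 2L)
    stop("rex_observed needs at least two points", call. = FALSE)
  ord <- order(profile$nu_cpmg_hz)
  r2 <- profile$r2eff_s[ord]
  k <- min(2L, floor(nrow(profile) / 2))
  mean(r2[seq_len(k)]) - mean(r2[seq(length(r2) - k + 1L, length(r2))])
}

#' Screen residues for conformational exchange
#'
#' Flags residues whose observed exchange contribution exceeds a threshold
#' at the stated field (default 18.8 T, where the shift difference in rad/s
#' and hence \eqn{R_{ex}} is largest).  A residue passes if any of its
#' methyls passes.
#'
#' @param dataset Long dispersion data frame.
#' @param threshold Screen threshold, s^-1 (default 5).
#' @param field_label Field at which to evaluate the screen.  If the label
#'   is absent from the dataset the field with the highest label-wise
#'   maximum rex would be ambiguous, so an error is raised.
#' @return Character vector of residue ids passing the screen.
#' @export
screen_dispersing <- function(dataset, threshold = 5,
                              field_label = "18.8T") {
  .check_dispersion_df(dataset)
  if (nrow(dataset) == 0L) stop("dataset is empty", call. = FALSE)
  if (!field_label %in% dataset$field_label) {
    have <- unique(dataset$field_label)
    if (length(have) == 1L) field_label <- have
    else stop("field label '", field_label, "' not present; dataset has: ",
              paste(have, collapse = ", "), call. = FALSE)
  }
  d <- collapse_duplicates(dataset[dataset$field_label == field_label, ,
                                   drop = FALSE])
  keys <- unique(d[c("residue_id", "methyl_id")])
  pass <- character()
  for (i in seq_len(nrow(keys))) {
    prof <- d[d$residue_id == keys$residue_id[i] &
                d$methyl_id == keys$methyl_id[i], , drop = FALSE]
    if (nrow(prof) >= 2L && rex_observed(prof) > threshold)
      pass <- union(pass, keys$residue_id[i])
  }
  sort(pass)
}

#' Read / write the tab-separated dispersion table
#'
#' Columns: `residue_id`, `aa`, `methyl_id`, `field_label`, `nu_cpmg_hz`,
#' `r2eff_s`, `sigma_s` (header required).  Duplicate measurements are
#' repeated rows.  Comment lines starting with `#` are ignored on read.
#'
#' @param path File path.
#' @return `read_dispersion_table()`: the dataset data frame.
#' @export
read_dispersion_table <- function(path) {
  x <- read.delim(path, header = TRUE, comment.char = "#",
                  stringsAsFactors = FALSE)
  .check_dispersion_df(x)
  x$residue_id <- as.character(x$residue_id)
  x$methyl_id <- as.character(x$methyl_id)
  x$field_label <- as.character(x$field_label)
  for (col in c("nu_cpmg_hz", "r2eff_s", "sigma_s"))
    x[[col]] <- as.numeric(x[[col]])
  x
}

#' @rdname read_dispersion_table
#' @param dataset Dataset data frame to write.
#' @export
write_dispersion_table <- function(dataset, path) {
  .check_dispersion_df(dataset)
  out <- dataset[.dispersion_cols]
  for (col in c("nu_cpmg_hz", "r2eff_s", "sigma_s"))
    out[[col]] <- sprintf("%.17g", out[[col]])   # lossless round trip
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an intensity-dialect table and build a dispersion dataset
#'
#' The intensity dialect has columns `residue_id`, `aa`, `methyl_id`,
#' `field_label`, `nu_cpmg_hz_or_REF` (the literal `REF` marks reference
#' rows), `intensity`, `replicate_index`.  Each (methyl, field) block is
#' converted with [r2eff_from_intensities()]; point errors are pooled from
#' the duplicate pairs via [estimate_sigma_from_duplicates()] applied to the
#' assembled dataset.
#'
#' @param path File path.
#' @param t_relax Constant relaxation period, s.
#' @return Dataset data frame (duplicates as repeated rows).
#' @export
read_intensity_table <- function(path, t_relax = 0.02) {
  x <- read.delim(path, header = TRUE, comment.char = "#",
                  stringsAsFactors = FALSE)
  need <- c("residue_id", "aa", "methyl_id", "field_label",
            "nu_cpmg_hz_or_REF", "intensity", "replicate_index")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stop("intensity table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  x$nu_cpmg_hz <- suppressWarnings(as.numeric(x$nu_cpmg_hz_or_REF))
  rows <- list()
  blocks <- unique(x[c("residue_id", "methyl_id", "field_label")])
  for (i in seq_len(nrow(blocks))) {
    sel <- x$residue_id == blocks$residue_id[i] &
      x$methyl_id == blocks$methyl_id[i] &
      x$field_label == blocks$field_label[i]
    rec <- x[sel, , drop = FALSE]
    is_ref <- is.na(rec$nu_cpmg_hz)
    i_ref <- mean(rec$intensity[is_ref])
    meas <- rec[!is_ref, , drop = FALSE]
    r2 <- -log(meas$intensity / i_ref) / t_relax
    rows[[i]] <- data.frame(residue_id = as.character(blocks$residue_id[i]),
                            aa = rec$aa[1], methyl_id = blocks$methyl_id[i],
                            field_label = blocks$field_label[i],
                            nu_cpmg_hz = meas$nu_cpmg_hz, r2eff_s = r2,
                            sigma_s = NA_real_)
  }
  out <- do.call(rbind, rows)
  sig <- estimate_sigma_from_duplicates(out)
  out$sigma_s <- as.numeric(sig[out$field_label])
  out
}
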