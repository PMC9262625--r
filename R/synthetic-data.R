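## Generator of dispersion datasets and methyl HMQC peak lists with the
## statistical structure of a two-field ILV-methyl study, providing ground
## truth for every pipeline stage.

#' Default field contexts (11.7 T and 18.8 T)
#'
#' 13C Larmor frequencies of 125.7 and 201.2 MHz, derived from 500 and
#' 800 MHz proton frequencies via the 13C/1H gyromagnetic ratio (~0.2515).
#'
#' @return Named list of [field_context()] objects.
#' @export
default_fields <- function() {
  list("11.7T" = field_context("11.7T", 125.7, 11.7),
       "18.8T" = field_context("18.8T", 201.2, 18.8))
}

#' Default CPMG schedule
#'
#' Constant relaxation period of 20 ms and 18 refocusing frequencies:
#' 17 roughly log-spaced values from 100 to 3000 s^-1 plus 6000 s^-1.
#' All values are multiples of 50 s^-1 so the even pulse count is exact.
#'
#' @return A [cpmg_schedule()].
#' @export
default_schedule <- function() {
  cpmg_schedule(c(100, 150, 200, 250, 300, 400, 500, 600, 700, 850, 1000,
                  1200, 1500, 1800, 2200, 2600, 3000, 6000),
                t_relax = 0.02)
}

.aa_methyls <- function(aa) {
  switch(aa, I = "d1", L = c("a", "b"), V = c("a", "b"),
         stop("unsupported amino acid: ", aa, call. = FALSE))
}

.residue_df <- function(ids) {
  data.frame(residue_id = ids, aa = substr(ids, 1, 1),
             stringsAsFactors = FALSE)
}

#' Specification of a synthetic dispersion dataset
#'
#' Describes the study design (fields, schedule, residues) and the planted
#' truth (clusters with shared exchange parameters, per-methyl shift-
#' difference and baseline ranges, noise level, duplicate positions).
#' Structural draws (dw, R2,0 per methyl) are controlled by `struct_seed`
#' so that the planted truth is a fixed property of the spec; the noise
#' realisation is controlled by `seed`.
#'
#' @param residues Data frame with columns `residue_id`, `aa` (I/L/V).
#' @param clusters List of lists with `members` (residue ids), `k_ex`,
#'   `p_B`.  Residues not in any cluster (or `off_cluster`) are generated
#'   exchange-free (`p_B = 0`), making the flat/exchange ground truth
#'   unambiguous.
#' @param off_cluster Optional named list residue_id -> list(k_ex, p_B) for
#'   residues that disperse but belong to no cluster.
#' @param fields Named list of [field_context()]s.
#' @param schedule A [cpmg_schedule()].
#' @param dw_range Range (ppm) from which per-methyl |dw| values of
#'   dispersing residues are drawn uniformly.
#' @param r20_range Named list of per-field c(min, max) baseline ranges.
#' @param noise_sigma Gaussian noise on R2,eff, s^-1 (default 0.3).
#' @param duplicate_nu Frequencies measured in duplicate (default 200 and
#'   6000 s^-1; the reference is duplicated in the intensity dialect).
#' @param min_rex Planted dispersing methyls are redrawn until their
#'   noiseless observed Rex at the screening field exceeds this value
#'   (default 8 s^-1), so that planted "dispersing" ground truth is
#'   well-defined.
#' @param screen_field Field label at which `min_rex` is enforced.
#' @param struct_seed Seed for structural draws.
#' @param seed Default noise seed used by [make_dispersion_dataset()].
#' @return An object of class `dataset_spec`.
#' @export
dataset_spec <- function(residues, clusters, off_cluster = list(),
                         fields = default_fields(),
                         schedule = default_schedule(),
                         dw_range = c(0.4, 1.6),
                         r20_range = list("11.7T" = c(10, 16),
                                          "18.8T" = c(12, 20)),
                         noise_sigma = 0.3, duplicate_nu = c(200, 6000),
                         min_rex = 8, screen_field = "18.8T",
                         struct_seed = 100L, seed = 1L) {
  stopifnot(is.data.frame(residues),
            all(c("residue_id", "aa") %in% names(residues)))
  members <- unlist(lapply(clusters, `[[`, "members"))
  if (anyDuplicated(c(members, names(off_cluster))))
    stop("cluster members must be disjoint", call. = FALSE)
  if (!all(c(members, names(off_cluster)) %in% residues$residue_id))
    stop("all cluster members must appear in residues", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (!screen_field %in% names(fields))
    screen_field <- names(fields)[length(fields)]
  structure(list(residues = residues, clusters = clusters,
                 off_cluster = off_cluster, fields = fields,
                 schedule = schedule, dw_range = dw_range,
                 r20_range = r20_range, noise_sigma = noise_sigma,
                 duplicate_nu = duplicate_nu, min_rex = min_rex,
                 screen_field = screen_field,
                 struct_seed = as.integer(struct_seed),
                 seed = as.integer(seed)),
            class = "dataset_spec")
}

## Deterministic planted truth for a spec: per-methyl exchange parameters,
## methyl-level cluster memberships, noiseless Rex at the screening field.
.ground_truth <- function(spec) {
  res <- spec$residues
  exch <- list()   # residue -> list(k_ex, p_B, cluster_index)
  for (ci in seq_along(spec$clusters)) {
    cl <- spec$clusters[[ci]]
    for (rid in cl$members)
      exch[[rid]] <- list(k_ex = cl$k_ex, p_B = cl$p_B, cluster = ci)
  }
  for (rid in names(spec$off_cluster)) {
    oc <- spec$off_cluster[[rid]]
    exch[[rid]] <- list(k_ex = oc$k_ex, p_B = oc$p_B, cluster = NA_integer_)
  }
  labels <- names(spec$fields)
  screen_fld <- spec$fields[[spec$screen_field]]
  params <- list()
  cluster_members <- lapply(spec$clusters, function(cl)
    list(members = character(), k_ex = cl$k_ex, p_B = cl$p_B))
  rex_rows <- list()
  .with_seed(spec$struct_seed, {
    for (i in seq_len(nrow(res))) {
      rid <- res$residue_id[i]; aa <- res$aa[i]
      for (mid in .aa_methyls(aa)) {
        key <- .methyl_key(rid, mid)
        r20 <- vapply(labels, function(fl)
          runif(1, spec$r20_range[[fl]][1], spec$r20_range[[fl]][2]), 0)
        names(r20) <- labels
        ex <- exch[[rid]]
        if (is.null(ex)) {
          params[[key]] <- exchange_params(1000, 0, 0, r20)
          rex <- 0
        } else {
          rex <- -Inf
          dw <- spec$dw_range[2]
          for (try in 1:100) {
            dw <- runif(1, spec$dw_range[1], spec$dw_range[2])
            pr <- exchange_params(ex$k_ex, ex$p_B, dw, r20)
            curve <- dispersion_curve(pr, screen_fld, spec$schedule)
            rex <- rex_observed(data.frame(nu_cpmg_hz = curve$nu_cpmg,
                                           r2eff_s = curve$r2eff))
            if (rex > spec$min_rex) break
          }
          params[[key]] <- exchange_params(ex$k_ex, ex$p_B, dw, r20)
          if (!is.na(ex$cluster))
            cluster_members[[ex$cluster]]$members <-
              c(cluster_members[[ex$cluster]]$members, key)
        }
        rex_rows[[key]] <- data.frame(key = key, residue_id = rid,
                                      rex_truth = max(rex, 0))
      }
    }
  })
  list(params = params, clusters = cluster_members,
       off_cluster_keys = unlist(lapply(names(spec$off_cluster), function(rid)
         .methyl_key(rid, .aa_methyls(substr(rid, 1, 1))))),
       dispersing_residues = sort(c(unlist(lapply(spec$clusters, `[[`,
                                                  "members")),
                                    names(spec$off_cluster))),
       rex_truth = do.call(rbind, rex_rows))
}

#' Generate a synthetic dispersion dataset
#'
#' Noiseless Bloch-McConnell curves for every methyl and field of the spec,
#' plus Gaussian noise at `noise_sigma`; the duplicate frequencies are
#' emitted twice (independent noise), as in a schedule with repeated
#' points.  The `sigma_s` column holds the pooled duplicate-based estimate
#' from [estimate_sigma_from_duplicates()], so the dataset is
#' self-contained.  Deterministic under `seed`.
#'
#' @param spec A [dataset_spec()].
#' @param seed Noise seed (defaults to `spec$seed`).
#' @return List with `dataset` (long data frame) and `truth` (per-methyl
#'   [exchange_params()], methyl-level cluster memberships, dispersing
#'   residues, noiseless Rex table).
#' @export
make_dispersion_dataset <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "dataset_spec"))
  truth <- .ground_truth(spec)
  labels <- names(spec$fields)
  nu <- spec$schedule$nu_cpmg
  rows <- list()
  .with_seed(seed, {
    for (key in names(truth$params)) {
      pr <- truth$params[[key]]
      rid <- truth$rex_truth[key, "residue_id"]
      aa <- substr(rid, 1, 1)
      mid <- sub(paste0("^", rid, "\\."), "", key)
      for (fl in labels) {
        curve <- bm_r2eff(pr, spec$fields[[fl]], spec$schedule)
        nu_all <- c(nu, intersect(spec$duplicate_nu, nu))
        mu <- c(curve, curve[match(intersect(spec$duplicate_nu, nu), nu)])
        noisy <- mu + rnorm(length(mu), 0, spec$noise_sigma)
        rows[[length(rows) + 1L]] <-
          data.frame(residue_id = rid, aa = aa, methyl_id = mid,
                     field_label = fl, nu_cpmg_hz = nu_all,
                     r2eff_s = noisy, sigma_s = NA_real_)
      }
    }
  })
  dataset <- do.call(rbind, rows)
  rownames(dataset) <- NULL
  sig <- tryCatch(estimate_sigma_from_duplicates(dataset),
                  error = function(e) setNames(rep(max(spec$noise_sigma, 0.1),
                                                   length(labels)), labels))
  dataset$sigma_s <- as.numeric(sig[dataset$field_label])
  list(dataset = dataset, truth = truth, spec = spec)
}

## -- study presets ------------------------------------------------------

.dbd_cluster1 <- c("L42", "V58", "L67", "L97", "I104", "V112", "I118",
                   "V124", "L131", "V147", "L170", "I185", "V226", "I237")
.dbd_cluster2 <- c("I139", "V210", "L212")
.dbd_flat <- c("V48", "L73", "I80", "L89", "V93", "I152", "L160", "V178",
               "I201", "V209", "L219", "V230", "L241")
.dd_flat <- c("L258", "V265", "I271", "L280", "V289", "I297", "L305",
              "V312", "I320", "L331", "V340", "L355")

#' Built-in study presets
#'
#' Dataset specs encoding the exchange regimes of an ILV-methyl study of
#' the NF-kB p50 Rel-homology-region homodimer and its DNA-binding domain:
#'
#' \describe{
#'   \item{`dbd_300K`}{Isolated DNA-binding domain at 300 K.  18 dispersing
#'     residues: a main cluster of 14 with k_ex = 1640 s^-1, p_B = 0.042, a
#'     second cluster (I139, V210, L212) with k_ex = 420 s^-1,
#'     p_B = 0.146, and L106 dispersing with an off-cluster rate.}
#'   \item{`rhr_300K`}{Full-length homodimer at 300 K.  19 dispersing
#'     residues: main cluster of 16 (k_ex = 1600 s^-1, p_B = 0.051),
#'     V210/L212 cluster (k_ex = 660 s^-1, p_B = 0.14), L106 off-cluster.}
#'   \item{`dbd_290K`}{DNA-binding domain at 290 K: one global process,
#'     k_ex = 480 s^-1, p_B = 0.029, over all 18 dispersing residues.}
#'   \item{`rhr_mhc_h2_bound`}{Homodimer bound to an 11-bp kB DNA duplex,
#'     measured at 18.8 T only: exchange of the loop-proximal residues is
#'     quenched (flat profiles); I104 and V233 retain free-like
#'     dispersion.}
#' }
#'
#' @param name Preset name.
#' @param seed Noise seed stored in the spec.
#' @param noise_sigma Noise level, s^-1 (default 0.3).
#' @return A [dataset_spec()].
#' @examples
#' sp <- preset("dbd_300K")
#' sp$clusters[[1]]$k_ex
#' @export
preset <- function(name = c("dbd_300K", "rhr_300K", "dbd_290K",
                            "rhr_mhc_h2_bound"),
                   seed = 1L, noise_sigma = 0.3) {
  if (length(name) != 1L || !name %in% c("dbd_300K", "rhr_300K", "dbd_290K",
                                         "rhr_mhc_h2_bound"))
    stop("unknown preset; available: dbd_300K, rhr_300K, dbd_290K, ",
         "rhr_mhc_h2_bound", call. = FALSE)
  if (name == "dbd_300K") {
    dataset_spec(
      residues = .residue_df(c(.dbd_cluster1, .dbd_cluster2, "L106",
                               .dbd_flat)),
      clusters = list(list(members = .dbd_cluster1, k_ex = 1640, p_B = 0.042),
                      list(members = .dbd_cluster2, k_ex = 420, p_B = 0.146)),
      off_cluster = list(L106 = list(k_ex = 5000, p_B = 0.10)),
      noise_sigma = noise_sigma, struct_seed = 101L, seed = seed)
  } else if (name == "rhr_300K") {
    dataset_spec(
      residues = .residue_df(c(.dbd_cluster1, "I139", "V233", "V210", "L212",
                               "L106", .dbd_flat, .dd_flat)),
      clusters = list(list(members = c(.dbd_cluster1, "I139", "V233"),
                           k_ex = 1600, p_B = 0.051),
                      list(members = c("V210", "L212"), k_ex = 660,
                           p_B = 0.14)),
      off_cluster = list(L106 = list(k_ex = 5000, p_B = 0.10)),
      noise_sigma = noise_sigma, struct_seed = 102L, seed = seed)
  } else if (name == "dbd_290K") {
    dataset_spec(
      residues = .residue_df(c(.dbd_cluster1, .dbd_cluster2, "L106",
                               .dbd_flat)),
      clusters = list(list(members = c(.dbd_cluster1, .dbd_cluster2, "L106"),
                           k_ex = 480, p_B = 0.029)),
      noise_sigma = noise_sigma, struct_seed = 103L, seed = seed)
  } else {
    ## DNA-bound homodimer: single field, loop-proximal exchange quenched
    loop_proximal <- c("L67", "L97", "I139", "V147", "V210", "L212", "I237")
    persistent <- c("I104", "V233")
    others <- setdiff(c(.dbd_cluster1, .dbd_cluster2, "L106", .dbd_flat),
                      c(loop_proximal, persistent))
    dataset_spec(
      residues = .residue_df(c(loop_proximal, persistent, others)),
      clusters = list(list(members = persistent, k_ex = 1600, p_B = 0.051)),
      fields = default_fields()["18.8T"],
      noise_sigma = noise_sigma, struct_seed = 104L, seed = seed)
  }
}

## -- synthetic methyl HMQC peak lists -----------------------------------

.peak_residues <- function() {
  .residue_df(c(.dbd_cluster1, .dbd_cluster2, "L106", .dbd_flat, .dd_flat))
}

.peak_keys <- function(res) {
  unlist(lapply(seq_len(nrow(res)), function(i)
    .methyl_key(res$residue_id[i], .aa_methyls(res$aa[i]))))
}

## Fixed free-state positions: per-amino-acid lattice with small jitter,
## spacing far beyond the matching tolerances so assignments are
## unambiguous.
.free_positions <- function() {
  res <- .peak_residues()
  keys <- .peak_keys(res)
  aa <- substr(keys, 1, 1)
  pos <- data.frame(assignment = keys, aa = aa,
                    methyl_id = sub("^.*\\.", "", keys),
                    dH_ppm = NA_real_, dC_ppm = NA_real_,
                    stringsAsFactors = FALSE)
  base_c <- c(I = 10, V = 19, L = 23)
  .with_seed(7001L, {
    for (a in c("I", "L", "V")) {
      idx <- which(aa == a)
      k <- seq_along(idx) - 1L
      pos$dH_ppm[idx] <- 0.25 + 0.13 * (k %% 8L) + runif(length(idx), -0.01, 0.01)
      pos$dC_ppm[idx] <- base_c[a] + 0.9 * (k %/% 8L) +
        runif(length(idx), -0.06, 0.06)
    }
  })
  pos$assignment <- sub("\\.", "", pos$assignment)  # e.g. "V112a", "I104d1"
  pos
}

.draw_offsets <- function(assignments, seed, h_max = 0.03, c_max = 0.18) {
  .with_seed(seed, {
    dh <- runif(length(assignments), 0.008, h_max) *
      sample(c(-1, 1), length(assignments), replace = TRUE)
    dc <- runif(length(assignments), 0.05, c_max) *
      sample(c(-1, 1), length(assignments), replace = TRUE)
    data.frame(assignment = assignments, dH = dh, dC = dc,
               stringsAsFactors = FALSE)
  })
}

.scenario_table <- function() {
  shifted <- c("L42", "V58", "L67", "L97", "V112", "V147", "V209", "I139",
               "I237")
  list(
    free = list(split = character(), shifted = character(), off = NULL),
    kB_proto = list(split = c("L42", "V58", "V112", "V147", "V209"),
                    shifted = setdiff(shifted, c("L42", "V58", "V112",
                                                 "V147", "V209")),
                    off_seed = 7004L, split_seeds = c(7002L, 7003L)),
    H2_kB = list(split = c("L67", "L97", "V112", "V209"),
                 shifted = setdiff(shifted, c("L67", "L97", "V112", "V209")),
                 off_seed = 7005L, split_seeds = c(7005L, 7006L)),
    MHC_H2 = list(split = character(), shifted = shifted, off_seed = 7007L),
    MHC_H2_M1 = list(split = character(), shifted = shifted, off_seed = 7008L),
    MHC_H2_M2 = list(split = shifted, shifted = character(),
                     split_seeds = c(7007L, 7008L))
  )
}

.split_pops <- function(residue) {
  switch(residue, V209 = c(0.5, 0.5), V112 = c(0.7, 0.3), c(0.6, 0.4))
}

.assignments_of <- function(pos, residues) {
  pos$assignment[sub("(a|b|d1)$", "", pos$assignment) %in% residues]
}

#' Generate free/bound methyl HMQC peak-list pairs
#'
#' Emulates six DNA-titration outcomes on a fixed free-state peak list:
#' `free` (bound identical to free), `kB_proto` and `H2_kB` (10-bp kB
#' duplexes: several residues split into two bound components with unequal
#' intensities, others shift), `MHC_H2` and `MHC_H2_M1` (11-bp symmetric
#' duplexes: one set of cross peaks, shifted), and `MHC_H2_M2` (asymmetric
#' 11-bp duplex: split peaks whose components coincide with the `MHC_H2`
#' and `MHC_H2_M1` bound positions, emulating binding in two orientations).
#' Peak positions and conformer offsets are deterministic; the seed only
#' controls intensity jitter.
#'
#' @param scenario One of `free`, `kB_proto`, `H2_kB`, `MHC_H2`,
#'   `MHC_H2_M1`, `MHC_H2_M2`.
#' @param seed Integer seed for intensity jitter.
#' @return List with `free` and `bound` peak-list data frames (columns
#'   `assignment`, `aa`, `methyl_id`, `dH_ppm`, `dC_ppm`, `intensity`;
#'   bound peaks are unassigned) and `truth` (split residues, per-component
#'   offsets and planted populations).
#' @export
make_peaklists <- function(scenario = c("free", "kB_proto", "H2_kB",
                                        "MHC_H2", "MHC_H2_M1", "MHC_H2_M2"),
                           seed = 1L) {
  tab <- .scenario_table()
  if (length(scenario) != 1L || !scenario %in% names(tab))
    stop("unknown scenario; available: ", paste(names(tab), collapse = ", "),
         call. = FALSE)
  sc <- tab[[scenario]]
  pos <- .free_positions()
  free <- pos
  free$intensity <- .with_seed(seed, exp(rnorm(nrow(pos), 0, 0.15)))
  attr(free, "state_label") <- "free"

  split_asn <- .assignments_of(pos, sc$split)
  shift_asn <- .assignments_of(pos, sc$shifted)
  off1 <- if (length(sc$split)) .draw_offsets(split_asn, sc$split_seeds[1])
  off2 <- if (length(sc$split)) .draw_offsets(split_asn, sc$split_seeds[2])
  offs <- if (length(sc$shifted)) .draw_offsets(shift_asn, sc$off_seed)

  boost <- if (scenario %in% c("MHC_H2", "MHC_H2_M1"))
    c("L67", "I139", "V210", "I237") else character()

  rows <- list()
  pops <- list()
  for (i in seq_len(nrow(pos))) {
    asn <- pos$assignment[i]
    res <- sub("(a|b|d1)$", "", asn)
    base <- pos[i, c("aa", "methyl_id", "dH_ppm", "dC_ppm")]
    inten <- free$intensity[i] * if (res %in% boost) 1.5 else 1
    if (asn %in% split_asn) {
      p <- .split_pops(res)
      o1 <- off1[off1$assignment == asn, ]
      o2 <- off2[off2$assignment == asn, ]
      rows[[length(rows) + 1L]] <-
        data.frame(assignment = "", aa = base$aa, methyl_id = base$methyl_id,
                   dH_ppm = base$dH_ppm + o1$dH, dC_ppm = base$dC_ppm + o1$dC,
                   intensity = inten * p[1])
      rows[[length(rows) + 1L]] <-
        data.frame(assignment = "", aa = base$aa, methyl_id = base$methyl_id,
                   dH_ppm = base$dH_ppm + o2$dH, dC_ppm = base$dC_ppm + o2$dC,
                   intensity = inten * p[2])
      pops[[asn]] <- p
    } else if (asn %in% shift_asn) {
      o <- offs[offs$assignment == asn, ]
      rows[[length(rows) + 1L]] <-
        data.frame(assignment = "", aa = base$aa, methyl_id = base$methyl_id,
                   dH_ppm = base$dH_ppm + o$dH, dC_ppm = base$dC_ppm + o$dC,
                   intensity = inten)
    } else {
      rows[[length(rows) + 1L]] <-
        data.frame(assignment = "", aa = base$aa, methyl_id = base$methyl_id,
                   dH_ppm = base$dH_ppm, dC_ppm = base$dC_ppm,
                   intensity = inten)
    }
  }
  bound <- do.call(rbind, rows)
  rownames(bound) <- NULL
  attr(bound, "state_label") <- scenario
  list(free = free, bound = bound,
       truth = list(split_residues = sc$split,
                    split_assignments = split_asn,
                    shifted_assignments = shift_asn,
                    populations = pops))
}
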