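## End-to-end orchestration: screen -> individual fits -> k_ex clustering ->
## cluster-global fits -> Monte Carlo uncertainties, plus the peak-list
## pipeline, with plain-text/TSV outputs for diffability.

#' Assemble a run configuration
#'
#' @param preset Name of a built-in [preset()], or `NULL` when `input` is
#'   given.
#' @param input Path to a dispersion table ([read_dispersion_table()]).
#' @param seed Integer seed controlling noise generation (for presets) and
#'   Monte Carlo resampling.
#' @param n_reps Monte Carlo replicates per cluster (default 100).
#' @param threshold_rex Screening threshold, s^-1 (default 5).
#' @param alpha F-test significance for model selection (default 0.01).
#' @param field_label Screening field (default `"18.8T"`).
#' @param gap_log10 Clustering gap cutoff on log10(k_ex).
#' @param noise_sigma Noise level for preset generation, s^-1.
#' @param out Optional output directory for TSV/summary files.
#' @return A list of class `run_config`.
#' @export
run_config <- function(preset = NULL, input = NULL, seed = 1L,
                       n_reps = 100L, threshold_rex = 5, alpha = 0.01,
                       field_label = "18.8T", gap_log10 = 0.25,
                       noise_sigma = 0.3, out = NULL) {
  if (is.null(preset) && is.null(input))
    stop("run_config needs a preset name or an input path", call. = FALSE)
  structure(list(preset = preset, input = input, seed = as.integer(seed),
                 n_reps = as.integer(n_reps), threshold_rex = threshold_rex,
                 alpha = alpha, field_label = field_label,
                 gap_log10 = gap_log10, noise_sigma = noise_sigma,
                 out = out),
            class = "run_config")
}

.fit_report_row <- function(fit, cluster_id, chi2_cluster) {
  p <- fit$params
  sig <- fit$param_sigmas
  data.frame(
    key = fit$key, residue_id = fit$residue_id, aa = fit$aa,
    methyl_id = fit$methyl_id, model = fit$model,
    k_ex = if (fit$model == "exchange") p$k_ex else NA_real_,
    p_B = if (fit$model == "exchange") p$p_B else NA_real_,
    dw_ppm = if (fit$model == "exchange") p$dw_ppm else NA_real_,
    r20_11_7 = if ("11.7T" %in% names(p$r20_by_field))
      p$r20_by_field[["11.7T"]] else NA_real_,
    r20_18_8 = if ("18.8T" %in% names(p$r20_by_field))
      p$r20_by_field[["18.8T"]] else NA_real_,
    k_ex_sigma = if (!is.null(sig)) sig[["k_ex"]] else NA_real_,
    p_B_sigma = if (!is.null(sig)) sig[["p_B"]] else NA_real_,
    chi2_individual = fit$chi2_reduced,
    chi2_cluster = chi2_cluster,
    cluster = cluster_id,
    converged = fit$converged,
    stringsAsFactors = FALSE)
}

#' Run the full dispersion-analysis pipeline
#'
#' Sequence: load or generate the dataset; pool point errors from
#' duplicates; screen residues by observed Rex at the screening field; fit
#' each passing methyl individually (exchange and flat models, F-test
#' selection); group exchange fits by k_ex; fit each candidate cluster
#' globally with the chi^2-ratio ejection rule; attempt to place leftover
#' exchange methyls into the fitted clusters (ties resolved towards the
#' lower cluster chi-square); estimate shared-parameter uncertainties by
#' Monte Carlo.  Deterministic given the config seed.
#'
#' @param config A [run_config()].
#' @return A list of class `pipeline_result`: `fits` (report data frame,
#'   one row per fitted methyl), `clusters` (list of `cpmg_cluster`),
#'   `cluster_table` (summary data frame), `screened` (residues passing the
#'   screen), `unclustered` (exchange methyls in no cluster), `summary`
#'   (named list echoing config, seed and decisions), and for preset runs
#'   `truth`.
#' @export
run_dispersion_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  fields <- default_fields()
  if (!is.null(config$preset)) {
    spec <- preset(config$preset, seed = config$seed,
                   noise_sigma = config$noise_sigma)
    gen <- make_dispersion_dataset(spec)
    dataset <- gen$dataset
    truth <- gen$truth
    fields <- spec$fields
    schedule <- spec$schedule
  } else {
    dataset <- read_dispersion_table(config$input)
    truth <- NULL
    schedule <- cpmg_schedule(sort(unique(dataset$nu_cpmg_hz)))
    have <- unique(dataset$field_label)
    fields <- fields[intersect(names(fields), have)]
    if (!all(have %in% names(fields)))
      stop("unknown field labels in input: ",
           paste(setdiff(have, names(fields)), collapse = ", "),
           call. = FALSE)
  }
  if (all(is.na(dataset$sigma_s)))
    dataset$sigma_s <- as.numeric(
      estimate_sigma_from_duplicates(dataset)[dataset$field_label])

  warnings_log <- character()
  screened <- screen_dispersing(dataset, threshold = config$threshold_rex,
                                field_label = config$field_label)

  sub <- dataset[dataset$residue_id %in% screened, , drop = FALSE]
  profs <- .profile_list(sub)
  fits <- list()
  models <- character()
  for (key in names(profs)) {
    dm <- sub[sub$residue_id == profs[[key]]$residue_id &
                sub$methyl_id == profs[[key]]$methyl_id, , drop = FALSE]
    fe <- fit_individual(dm, fields, schedule)
    ff <- fit_flat(dm, fields, schedule)
    if (!isTRUE(fe$converged))
      warnings_log <- c(warnings_log,
                        paste0("individual fit did not converge: ", key))
    choice <- model_select(fe, ff, dm, alpha = config$alpha,
                           rex_threshold = config$threshold_rex,
                           field_label = config$field_label)
    fits[[key]] <- if (choice == "exchange") fe else ff
    models[key] <- as.character(choice)
  }

  exch_keys <- names(fits)[models == "exchange"]
  candidates <- cluster_by_kex(fits[exch_keys],
                               gap_log10 = config$gap_log10)
  clusters <- list()
  clustered <- character()
  for (cand in candidates) {
    cl <- fit_cluster_global(sub, cand, fits, fields, schedule)
    if (length(cl$members) >= 2L) {
      clusters[[length(clusters) + 1L]] <- cl
      clustered <- c(clustered, cl$members)
    } else {
      warnings_log <- c(warnings_log,
                        paste0("candidate cluster collapsed: ",
                               paste(cand, collapse = ", ")))
    }
  }

  ## rescue pass: try leftover exchange methyls in each fitted cluster
  leftover <- setdiff(exch_keys, clustered)
  if (length(clusters) > 0 && length(leftover) > 0) {
    gained <- rep(FALSE, length(clusters))
    for (key in leftover) {
      trials <- lapply(clusters, function(cl)
        try_assign_member(cl, sub, key, fits[[key]], fields, schedule))
      ok <- vapply(trials, `[[`, TRUE, "accept")
      if (any(ok)) {
        chis <- vapply(trials, `[[`, 0, "chi2_cluster")
        chis[!ok] <- Inf
        best <- which.min(chis)
        cl <- clusters[[best]]
        cl$members <- c(cl$members, key)
        cl$per_member[[key]] <- trials[[best]][c("dw_ppm", "r20_by_field")]
        cl$chi2_cluster_by_member[key] <- trials[[best]]$chi2_cluster
        clusters[[best]] <- cl
        clustered <- c(clustered, key)
        gained[best] <- TRUE
      }
    }
    ## refit clusters that gained members, re-running the ejection rule
    for (i in which(gained))
      clusters[[i]] <- fit_cluster_global(sub, clusters[[i]]$members,
                                          fits, fields, schedule)
  }
  ## order clusters by size, largest first
  if (length(clusters) > 1L)
    clusters <- clusters[order(vapply(clusters, function(c)
      length(c$members), 0L), decreasing = TRUE)]

  if (config$n_reps > 0) {
    for (i in seq_along(clusters)) {
      clusters[[i]] <- monte_carlo_sigmas(clusters[[i]], sub, fields,
                                          schedule, n_reps = config$n_reps,
                                          seed = config$seed + 7919L * i)
    }
  }

  unclustered <- setdiff(exch_keys, unlist(lapply(clusters, `[[`, "members")))
  rows <- list()
  for (key in names(fits)) {
    cid <- NA_integer_; c2c <- NA_real_
    for (i in seq_along(clusters)) {
      if (key %in% clusters[[i]]$members) {
        cid <- i
        c2c <- clusters[[i]]$chi2_cluster_by_member[[key]]
      }
    }
    rows[[key]] <- .fit_report_row(fits[[key]], cid, c2c)
  }
  fit_report <- do.call(rbind, rows)
  rownames(fit_report) <- NULL

  cluster_table <- if (length(clusters) > 0) do.call(rbind, lapply(
    seq_along(clusters), function(i) {
      cl <- clusters[[i]]
      data.frame(cluster = i, n_members = length(cl$members),
                 k_ex = cl$k_ex,
                 k_ex_sigma = if (!is.null(cl$param_sigmas))
                   cl$param_sigmas[["k_ex"]] else NA_real_,
                 p_B = cl$p_B,
                 p_B_sigma = if (!is.null(cl$param_sigmas))
                   cl$param_sigmas[["p_B"]] else NA_real_,
                 members = paste(cl$members, collapse = ","),
                 ejected = paste(cl$ejected, collapse = ","))
    })) else data.frame()

  summary <- list(
    preset = if (is.null(config$preset)) "" else config$preset,
    input = if (is.null(config$input)) "" else config$input,
    seed = config$seed, n_reps = config$n_reps,
    threshold_rex = config$threshold_rex, alpha = config$alpha,
    screen_field = config$field_label, gap_log10 = config$gap_log10,
    t_relax = schedule$t_relax,
    nu_cpmg = paste(schedule$nu_cpmg, collapse = ","),
    n_screened = length(screened),
    screened = paste(screened, collapse = ","),
    n_clusters = length(clusters),
    unclustered = paste(unclustered, collapse = ","),
    warnings = paste(warnings_log, collapse = "; "))

  out <- structure(list(fits = fit_report, clusters = clusters,
                        cluster_table = cluster_table, screened = screened,
                        unclustered = unclustered, summary = summary,
                        truth = truth, dataset = dataset),
                   class = "pipeline_result")
  if (!is.null(config$out)) .write_pipeline_outputs(out, config)
  out
}

.write_summary <- function(summary, path) {
  lines <- vapply(names(summary), function(k)
    paste0(k, ": ", summary[[k]]), "")
  writeLines(lines, path)
  invisible(path)
}

.write_pipeline_outputs <- function(result, config) {
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  write.table(result$fits, file.path(config$out, "fits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (nrow(result$cluster_table) > 0)
    write.table(result$cluster_table, file.path(config$out, "clusters.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write_dispersion_table(result$dataset,
                         file.path(config$out, "dataset.tsv"))
  .write_summary(result$summary, file.path(config$out, "summary.txt"))
  invisible(config$out)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d residues screened, %d clusters, %d unclustered exchange methyls\n",
              length(x$screened), length(x$clusters), length(x$unclustered)))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    se <- cl$param_sigmas
    cat(sprintf("  cluster %d (%d methyls): k_ex = %.0f%s s-1, p_B = %.3f%s\n",
                i, length(cl$members), cl$k_ex,
                if (!is.null(se)) sprintf(" +/- %.0f", se[["k_ex"]]) else "",
                cl$p_B,
                if (!is.null(se)) sprintf(" +/- %.3f", se[["p_B"]]) else ""))
  }
  invisible(x)
}

#' Run the peak-list comparison pipeline
#'
#' Transfers assignments from the free to the bound peak list, reports
#' per-assignment CSPs and split flags, and classifies the complex as a
#' single or multiple bound conformation.
#'
#' @param scenario Name of a built-in [make_peaklists()] scenario, or
#'   `NULL` when file paths are given.
#' @param free_path,bound_path Paths to peak-list files (ignored when
#'   `scenario` is given).
#' @param seed Intensity-jitter seed for scenario generation.
#' @param tol_h,tol_c Matching tolerances, ppm.
#' @param min_split Split-assignment count for the multiple-conformation
#'   verdict.
#' @param out Optional output directory.
#' @return List with `report` (`match_report`), `classification`,
#'   `csp_table` and `summary`.
#' @export
run_peaks_pipeline <- function(scenario = NULL, free_path = NULL,
                               bound_path = NULL, seed = 1L, tol_h = 0.05,
                               tol_c = 0.3, min_split = 2L, out = NULL) {
  if (!is.null(scenario)) {
    pl <- make_peaklists(scenario, seed = seed)
    free <- pl$free; bound <- pl$bound
  } else {
    if (is.null(free_path) || is.null(bound_path))
      stop("need a scenario or both free and bound paths", call. = FALSE)
    free <- read_peaklist(free_path, "free")
    bound <- read_peaklist(bound_path, "bound")
  }
  report <- transfer_assignments(free, bound, tol_h = tol_h, tol_c = tol_c)
  classification <- classify_complex(report, min_split = min_split)
  csp <- report$by_assignment
  summary <- list(scenario = if (is.null(scenario)) "" else scenario,
                  seed = seed, tol_h = tol_h, tol_c = tol_c,
                  min_split = min_split,
                  n_assignments = nrow(csp),
                  n_split = sum(csp$split),
                  n_unmatched_target = nrow(report$unmatched_target),
                  classification = as.character(classification))
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write.table(csp, file.path(out, "csp_report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(report$matches, file.path(out, "matches.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    .write_summary(summary, file.path(out, "summary.txt"))
  }
  list(report = report, classification = classification, csp_table = csp,
       summary = summary)
}
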