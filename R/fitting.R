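## Per-methyl and cluster-global weighted least-squares fitting of the
## two-site model, flat-vs-exchange model selection, k_ex-based clustering
## with the chi^2-ratio acceptance rule, and Monte Carlo uncertainties.

#' Default multi-start grid for individual fits
#'
#' Covers the exchange regimes typically seen for methyl 13C: k_ex from
#' slow-intermediate to fast, sparse to moderately populated excited states,
#' small to large shift differences.
#'
#' @return List with numeric vectors `k_ex`, `p_B`, `dw_ppm`.
#' @export
default_start_grid <- function() {
  list(k_ex = c(200, 600, 1600, 4000),
       p_B = c(0.01, 0.05, 0.15),
       dw_ppm = c(0.3, 1.0, 2.0))
}

#' Default parameter bounds (physical ranges for methyl 13C)
#'
#' @return List with `lower` and `upper` named numeric vectors for
#'   `k_ex`, `p_B`, `dw_ppm`, `r20`.
#' @export
default_bounds <- function() {
  list(lower = c(k_ex = 10, p_B = 1e-4, dw_ppm = 1e-4, r20 = 1e-3),
       upper = c(k_ex = 2e4, p_B = 0.499, dw_ppm = 6, r20 = 200))
}

## Turn a (collapsed) dataset into a per-methyl structure:
## list(key -> list(residue_id, aa, methyl_id, fields = list(label ->
##      list(nu, r2, sigma))))
.profile_list <- function(dataset) {
  d <- collapse_duplicates(dataset)
  keys <- unique(d[c("residue_id", "aa", "methyl_id")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- d$residue_id == keys$residue_id[i] &
      d$methyl_id == keys$methyl_id[i]
    di <- d[sel, , drop = FALSE]
    flds <- list()
    for (fl in unique(di$field_label)) {
      dd <- di[di$field_label == fl, , drop = FALSE]
      flds[[fl]] <- list(nu = dd$nu_cpmg_hz, r2 = dd$r2eff_s,
                         sigma = dd$sigma_s)
    }
    key <- .methyl_key(keys$residue_id[i], keys$methyl_id[i])
    out[[key]] <- list(residue_id = keys$residue_id[i], aa = keys$aa[i],
                       methyl_id = keys$methyl_id[i], fields = flds)
  }
  out
}

## Residuals of the exchange model for one methyl.
## p = c(k_ex, p_B, dw_ppm, r20 for each field label in `labels` order)
.res_exchange <- function(p, prof, fields, labels, t_relax) {
  out <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    fl <- labels[i]
    fp <- prof$fields[[fl]]
    dw_rad <- p[3] * 2 * pi * fields[[fl]]$larmor_13c_mhz
    mod <- .bm_core(p[1], p[2], dw_rad, p[3 + i], t_relax, fp$nu)
    out[[i]] <- (mod - fp$r2) / fp$sigma
  }
  unlist(out, use.names = FALSE)
}

.n_points <- function(prof) sum(vapply(prof$fields, function(f) length(f$nu), 0L))

#' Fit one methyl group's dispersion profiles to the two-site model
#'
#' Weighted nonlinear least squares over \{k_ex, p_B, dw_ppm, one R2,0 per
#' field\}, fitted jointly against all fields of the methyl (the shift
#' difference in ppm is shared across fields; per-field rad/s values follow
#' from the field contexts).  Initialisation is multi-start: the objective
#' is evaluated on the start grid crossed with per-field R2,0 starts taken
#' from the mean of the three highest-frequency points, and full
#' optimisation (Levenberg-Marquardt, [minpack.lm::nls.lm()]) is run from
#' the `n_best` most promising starts.
#'
#' @param data_methyl Dataset rows for one methyl (any number of fields).
#' @param fields Named list of [field_context()] objects keyed by label.
#' @param schedule A [cpmg_schedule()] (supplies `t_relax`).
#' @param start_grid See [default_start_grid()].
#' @param bounds See [default_bounds()].
#' @param n_best Number of grid starts from which full optimisation is run.
#' @return An object of class `cpmg_fit`: fitted [exchange_params()],
#'   `chi2`, `chi2_reduced`, `n_free`, `n_points`, `model = "exchange"`,
#'   `converged`, and `param_sigmas` (`NULL` until
#'   [monte_carlo_sigmas()] is run).
#' @export
fit_individual <- function(data_methyl, fields, schedule,
                           start_grid = default_start_grid(),
                           bounds = default_bounds(), n_best = 8L) {
  prof <- .profile_list(data_methyl)
  if (length(prof) != 1L)
    stop("data_methyl must contain exactly one methyl group", call. = FALSE)
  prof <- prof[[1L]]
  labels <- names(prof$fields)
  if (!all(labels %in% names(fields)))
    stop("missing field context for: ",
         paste(setdiff(labels, names(fields)), collapse = ", "),
         call. = FALSE)
  n_free <- 3L + length(labels)
  n_pts <- .n_points(prof)
  if (n_pts < n_free)
    stop("fewer points (", n_pts, ") than free parameters (", n_free, ")",
         call. = FALSE)
  t_relax <- schedule$t_relax

  r20_start <- vapply(labels, function(fl) {
    fp <- prof$fields[[fl]]
    mean(fp$r2[order(fp$nu, decreasing = TRUE)][seq_len(min(3L, length(fp$nu)))])
  }, 0)
  r20_start <- pmin(pmax(r20_start, bounds$lower["r20"] + 1e-3),
                    bounds$upper["r20"])

  starts <- expand.grid(k_ex = start_grid$k_ex, p_B = start_grid$p_B,
                        dw_ppm = start_grid$dw_ppm)
  sse <- vapply(seq_len(nrow(starts)), function(i) {
    p <- c(unlist(starts[i, ]), r20_start)
    sum(.res_exchange(p, prof, fields, labels, t_relax)^2)
  }, 0)
  take <- order(sse)[seq_len(min(n_best, nrow(starts)))]

  lower <- c(bounds$lower[c("k_ex", "p_B", "dw_ppm")],
             rep(bounds$lower["r20"], length(labels)))
  upper <- c(bounds$upper[c("k_ex", "p_B", "dw_ppm")],
             rep(bounds$upper["r20"], length(labels)))

  best <- NULL
  for (i in take) {
    p0 <- c(unlist(starts[i, ]), r20_start)
    fit <- tryCatch(
      nls.lm(par = p0, fn = .res_exchange, prof = prof, fields = fields,
             labels = labels, t_relax = t_relax, lower = lower,
             upper = upper, control = nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    conv <- fit$info %in% 1:4
    chi2 <- fit$deviance
    if (is.null(best) || (conv && !best$conv) ||
        (conv == best$conv && chi2 < best$chi2))
      best <- list(par = fit$par, chi2 = chi2, conv = conv)
  }
  if (is.null(best))
    return(structure(list(key = .methyl_key(prof$residue_id, prof$methyl_id),
                          residue_id = prof$residue_id, aa = prof$aa,
                          methyl_id = prof$methyl_id, model = "exchange",
                          params = NULL, chi2 = NA_real_,
                          chi2_reduced = NA_real_, n_free = n_free,
                          n_points = n_pts, converged = FALSE,
                          param_sigmas = NULL),
                     class = "cpmg_fit"))
  p <- best$par
  params <- exchange_params(p[1], p[2], p[3],
                            setNames(p[3 + seq_along(labels)], labels))
  structure(list(key = .methyl_key(prof$residue_id, prof$methyl_id),
                 residue_id = prof$residue_id, aa = prof$aa,
                 methyl_id = prof$methyl_id, model = "exchange",
                 params = params, chi2 = best$chi2,
                 chi2_reduced = best$chi2 / max(1L, n_pts - n_free),
                 n_free = n_free, n_points = n_pts,
                 converged = best$conv, param_sigmas = NULL,
                 field_labels = labels),
            class = "cpmg_fit")
}

#' Fit the exchange-free (flat) model
#'
#' One baseline R2,0 per field (the weighted mean), no exchange.  The
#' returned parameter set has `p_B = 0`.
#'
#' @inheritParams fit_individual
#' @return A `cpmg_fit` with `model = "flat"`.
#' @export
fit_flat <- function(data_methyl, fields, schedule) {
  prof <- .profile_list(data_methyl)
  stopifnot(length(prof) == 1L)
  prof <- prof[[1L]]
  labels <- names(prof$fields)
  chi2 <- 0
  r20 <- setNames(numeric(length(labels)), labels)
  for (fl in labels) {
    fp <- prof$fields[[fl]]
    w <- 1 / fp$sigma^2
    r20[fl] <- weighted.mean(fp$r2, w)
    chi2 <- chi2 + sum(((fp$r2 - r20[fl]) / fp$sigma)^2)
  }
  n_pts <- .n_points(prof)
  n_free <- length(labels)
  params <- exchange_params(default_bounds()$lower["k_ex"], 0, 0, pmax(r20, 0))
  structure(list(key = .methyl_key(prof$residue_id, prof$methyl_id),
                 residue_id = prof$residue_id, aa = prof$aa,
                 methyl_id = prof$methyl_id, model = "flat",
                 params = params, chi2 = chi2,
                 chi2_reduced = chi2 / max(1L, n_pts - n_free),
                 n_free = n_free, n_points = n_pts, converged = TRUE,
                 param_sigmas = NULL, field_labels = labels),
            class = "cpmg_fit")
}

#' @export
print.cpmg_fit <- function(x, ...) {
  cat(sprintf("<cpmg_fit> %s  model=%s  chi2_red=%.3g  converged=%s\n",
              x$key, x$model, x$chi2_reduced, x$converged))
  if (!is.null(x$params) && x$model == "exchange") print(x$params)
  invisible(x)
}

#' Choose between the exchange and flat models
#'
#' An F-test on the reduction in weighted chi-square guards against
#' overfitting flat profiles; the exchange model is chosen only when the
#' test is significant at `alpha` and the observed \eqn{R_{ex}} (at the
#' screening field) exceeds `rex_threshold`.
#'
#' @param exchange_fit,flat_fit `cpmg_fit` objects for the same data.
#' @param data_methyl The data both models were fitted to.
#' @param alpha Significance level (default 0.01).
#' @param rex_threshold Screening threshold on observed Rex, s^-1.
#' @param field_label Field at which Rex is evaluated (falls back to the
#'   only available field).
#' @return `"exchange"` or `"flat"`, with attributes `p_value` and
#'   `rex_observed`.
#' @export
model_select <- function(exchange_fit, flat_fit, data_methyl, alpha = 0.01,
                         rex_threshold = 5, field_label = "18.8T") {
  stopifnot(inherits(exchange_fit, "cpmg_fit"), inherits(flat_fit, "cpmg_fit"))
  d <- collapse_duplicates(data_methyl)
  if (!field_label %in% d$field_label) field_label <- d$field_label[1L]
  prof <- d[d$field_label == field_label, , drop = FALSE]
  rex <- if (nrow(prof) >= 2L) rex_observed(prof) else 0

  n <- exchange_fit$n_points
  k1 <- flat_fit$n_free
  k2 <- exchange_fit$n_free
  df2 <- n - k2
  p_val <- 1
  if (exchange_fit$converged && df2 > 0 && k2 > k1) {
    if (exchange_fit$chi2 < 1e-12) {
      p_val <- if (flat_fit$chi2 > 1e-12) 0 else 1
    } else {
      f_stat <- ((flat_fit$chi2 - exchange_fit$chi2) / (k2 - k1)) /
        (exchange_fit$chi2 / df2)
      p_val <- pf(f_stat, k2 - k1, df2, lower.tail = FALSE)
    }
  }
  choice <- if (p_val < alpha && rex > rex_threshold) "exchange" else "flat"
  attr(choice, "p_value") <- p_val
  attr(choice, "rex_observed") <- rex
  choice
}

#' Group methyls into candidate clusters by exchange rate
#'
#' One-dimensional single-linkage grouping of \eqn{\log_{10} k_{ex}} from
#' the individual fits: sorted values are split wherever consecutive values
#' differ by more than `gap_log10`.  Groups with at least two members are
#' returned as candidates, largest first; singletons stay with their
#' individual fits.
#'
#' Candidate groups must also span at least two residues: the prochiral
#' methyls of one residue report on the same site, so a group containing a
#' single residue is no evidence of a collective process and its members
#' stay with their individual fits.
#'
#' @param fits List of converged exchange-model `cpmg_fit` objects.
#' @param gap_log10 Gap cutoff on log10(k_ex) (default 0.25).
#' @return List of character vectors of methyl keys (possibly empty).
#' @export
cluster_by_kex <- function(fits, gap_log10 = 0.25) {
  fits <- Filter(function(f) f$model == "exchange" && isTRUE(f$converged),
                 fits)
  if (length(fits) < 2L) return(list())
  kex <- vapply(fits, function(f) f$params$k_ex, 0)
  keys <- unname(vapply(fits, function(f) f$key, ""))
  rids <- unname(vapply(fits, function(f) f$residue_id, ""))
  ord <- order(kex)
  lk <- log10(kex[ord])
  grp <- cumsum(c(0, diff(lk) > gap_log10))
  cand <- split(keys[ord], grp)
  rid_of <- setNames(rids, keys)
  cand <- Filter(function(m) length(m) >= 2L &&
                   length(unique(rid_of[m])) >= 2L, cand)
  cand <- cand[order(vapply(cand, length, 0L), decreasing = TRUE)]
  lapply(unname(cand), unname)
}

#' Chi-square-ratio acceptance rule for cluster membership
#'
#' A methyl belongs in a cluster when fitting it with the cluster's shared
#' (k_ex, p_B) does not degrade its reduced chi-square by a factor of two
#' or more: accept iff `chi2_cluster / chi2_individual < 2` (strict).  When
#' the individual fit is perfect (`chi2_individual = 0`) the ratio is
#' treated as 1 if the cluster fit is also essentially perfect (within
#' 1e-12), otherwise the member is rejected.
#'
#' @param chi2_cluster Reduced chi-square under shared cluster parameters.
#' @param chi2_individual Reduced chi-square of the independent fit.
#' @return Logical.
#' @export
accept_member <- function(chi2_cluster, chi2_individual) {
  if (chi2_individual <= 0)
    return(chi2_cluster < 1e-12)
  (chi2_cluster / chi2_individual) < 2
}

## --- cluster-global fit internals ------------------------------------

## Parameter packing: p[1] = k_ex, p[2] = p_B, then for each member (in
## `members` order) dw_ppm followed by one r20 per field label of that
## member.  `layout` records the index map.
.cluster_layout <- function(profs) {
  idx <- list(); at <- 3L
  for (key in names(profs)) {
    labels <- names(profs[[key]]$fields)
    idx[[key]] <- list(dw = at, r20 = setNames(at + seq_along(labels), labels),
                       labels = labels)
    at <- at + 1L + length(labels)
  }
  list(idx = idx, n_par = at - 1L)
}

.member_res <- function(p, prof, mi, fields, t_relax) {
  out <- vector("list", length(mi$labels))
  for (i in seq_along(mi$labels)) {
    fl <- mi$labels[i]
    fp <- prof$fields[[fl]]
    dw_rad <- p[mi$dw] * 2 * pi * fields[[fl]]$larmor_13c_mhz
    mod <- .bm_core(p[1], p[2], dw_rad, p[mi$r20[[fl]]], t_relax, fp$nu)
    out[[i]] <- (mod - fp$r2) / fp$sigma
  }
  unlist(out, use.names = FALSE)
}

.cluster_res <- function(p, profs, layout, fields, t_relax) {
  unlist(lapply(names(profs), function(key)
    .member_res(p, profs[[key]], layout$idx[[key]], fields, t_relax)),
    use.names = FALSE)
}

## Forward-difference Jacobian exploiting the block structure: the two
## shared parameters touch every residual; each member parameter touches
## only that member's rows.
.cluster_jac <- function(p, profs, layout, fields, t_relax) {
  base <- .cluster_res(p, profs, layout, fields, t_relax)
  n <- length(base)
  jac <- matrix(0, n, layout$n_par)
  rows <- list(); at <- 0L
  for (key in names(profs)) {
    len <- .n_points(profs[[key]])
    rows[[key]] <- at + seq_len(len)
    at <- at + len
  }
  for (j in 1:2) {
    h <- 1e-6 * max(abs(p[j]), 1e-2)
    pp <- p; pp[j] <- pp[j] + h
    jac[, j] <- (.cluster_res(pp, profs, layout, fields, t_relax) - base) / h
  }
  for (key in names(profs)) {
    mi <- layout$idx[[key]]
    b_m <- base[rows[[key]]]
    for (j in c(mi$dw, unlist(mi$r20))) {
      h <- 1e-6 * max(abs(p[j]), 1e-2)
      pp <- p; pp[j] <- pp[j] + h
      jac[rows[[key]], j] <-
        (.member_res(pp, profs[[key]], mi, fields, t_relax) - b_m) / h
    }
  }
  jac
}

.fit_cluster_once <- function(profs, p0, layout, fields, t_relax, bounds) {
  lower <- c(bounds$lower[c("k_ex", "p_B")], rep(NA_real_, layout$n_par - 2L))
  upper <- c(bounds$upper[c("k_ex", "p_B")], rep(NA_real_, layout$n_par - 2L))
  for (key in names(profs)) {
    mi <- layout$idx[[key]]
    lower[mi$dw] <- bounds$lower["dw_ppm"]; upper[mi$dw] <- bounds$upper["dw_ppm"]
    lower[unlist(mi$r20)] <- bounds$lower["r20"]
    upper[unlist(mi$r20)] <- bounds$upper["r20"]
  }
  fit <- nls.lm(par = p0, fn = .cluster_res, jac = .cluster_jac,
                profs = profs, layout = layout, fields = fields,
                t_relax = t_relax, lower = unname(lower),
                upper = unname(upper),
                control = nls.lm.control(maxiter = 300))
  fit
}

#' Cluster-global fit with shared exchange parameters
#'
#' Joint weighted least squares over all members of a candidate cluster:
#' one shared (k_ex, p_B) plus per-member shift difference and per-field
#' baselines.  After convergence each member's reduced chi-square under the
#' shared parameters is compared with its individual fit through
#' [accept_member()]; the worst violator of the chi^2-ratio rule is ejected
#' and the fit repeated until the membership is stable.  Ejected methyls are
#' reported and keep their individual fits.
#'
#' @param dataset Dataset containing the members' profiles.
#' @param members Character vector of methyl keys (>= 2).
#' @param individual_fits Named list of `cpmg_fit` objects (by key)
#'   providing chi2_individual and per-member starting values.
#' @param fields Named list of [field_context()] objects.
#' @param schedule A [cpmg_schedule()].
#' @param bounds See [default_bounds()].
#' @return An object of class `cpmg_cluster`: `members`, shared `k_ex` and
#'   `p_B`, `per_member` (dw_ppm and per-field R2,0),
#'   `chi2_cluster_by_member`, `chi2_individual_by_member`, `ejected`,
#'   `trace` (total objective per ejection round), `converged`,
#'   `param_sigmas` (filled by [monte_carlo_sigmas()]).  With fewer than two
#'   surviving members an empty cluster (`members = character(0)`) is
#'   returned with a `diagnostic` field.
#' @export
fit_cluster_global <- function(dataset, members, individual_fits, fields,
                               schedule, bounds = default_bounds()) {
  if (length(members) < 2L)
    stop("a candidate cluster needs at least two members", call. = FALSE)
  all_profs <- .profile_list(dataset)
  if (!all(members %in% names(all_profs)))
    stop("dataset lacks profiles for: ",
         paste(setdiff(members, names(all_profs)), collapse = ", "),
         call. = FALSE)
  t_relax <- schedule$t_relax
  chi2_ind <- vapply(members, function(k) individual_fits[[k]]$chi2_reduced, 0)
  active <- members
  ejected <- character()
  trace <- numeric()
  repeat {
    profs <- all_profs[active]
    layout <- .cluster_layout(profs)
    p0 <- numeric(layout$n_par)
    kex0 <- median(vapply(active, function(k) individual_fits[[k]]$params$k_ex, 0))
    pb0 <- median(vapply(active, function(k) individual_fits[[k]]$params$p_B, 0))
    p0[1] <- kex0; p0[2] <- pb0
    for (key in active) {
      mi <- layout$idx[[key]]
      pm <- individual_fits[[key]]$params
      p0[mi$dw] <- max(pm$dw_ppm, bounds$lower["dw_ppm"] * 2)
      for (fl in mi$labels)
        p0[mi$r20[[fl]]] <- pm$r20_by_field[[fl]]
    }
    fit <- .fit_cluster_once(profs, p0, layout, fields, t_relax, bounds)
    trace <- c(trace, fit$deviance)

    chi2_cl <- setNames(numeric(length(active)), active)
    for (key in active) {
      mi <- layout$idx[[key]]
      res_m <- .member_res(fit$par, profs[[key]], mi, fields, t_relax)
      dof <- max(1L, .n_points(profs[[key]]) - (3L + length(mi$labels)))
      chi2_cl[key] <- sum(res_m^2) / dof
    }
    ## floor the denominator so numerically perfect individual fits
    ## (chi2 ~ machine precision) do not defeat the ratio rule
    denom <- pmax(chi2_ind[active], 1e-9)
    ok <- vapply(active, function(k) accept_member(chi2_cl[k], denom[k]),
                 TRUE)
    if (all(ok)) break
    ratios <- chi2_cl / denom
    worst <- active[which.max(ratios)]
    ejected <- c(ejected, worst)
    active <- setdiff(active, worst)
    if (length(active) < 2L)
      return(structure(list(members = character(0), k_ex = NA_real_,
                            p_B = NA_real_, per_member = list(),
                            chi2_cluster_by_member = numeric(),
                            chi2_individual_by_member = chi2_ind,
                            ejected = ejected, trace = trace,
                            converged = FALSE, param_sigmas = NULL,
                            diagnostic = "all members ejected by the chi2-ratio rule"),
                       class = "cpmg_cluster"))
  }
  layout <- .cluster_layout(all_profs[active])
  per_member <- list()
  for (key in active) {
    mi <- layout$idx[[key]]
    per_member[[key]] <- list(
      dw_ppm = fit$par[mi$dw],
      r20_by_field = setNames(fit$par[unlist(mi$r20)], mi$labels))
  }
  structure(list(members = unname(active), k_ex = unname(fit$par[1]),
                 p_B = unname(fit$par[2]),
                 per_member = per_member,
                 chi2_cluster_by_member = chi2_cl[active],
                 chi2_individual_by_member = chi2_ind,
                 ejected = ejected, trace = trace,
                 converged = fit$info %in% 1:4, chi2 = fit$deviance,
                 param_sigmas = NULL, field_labels_by_member =
                   lapply(layout$idx[active], `[[`, "labels")),
            class = "cpmg_cluster")
}

#' @export
print.cpmg_cluster <- function(x, ...) {
  if (length(x$members) == 0L) {
    cat("<cpmg_cluster> empty (", x$diagnostic, ")\n")
    return(invisible(x))
  }
  se <- x$param_sigmas
  cat(sprintf("<cpmg_cluster> %d members: k_ex = %.4g%s s-1, p_B = %.4g%s\n",
              length(x$members), x$k_ex,
              if (!is.null(se)) sprintf(" +/- %.2g", se[["k_ex"]]) else "",
              x$p_B,
              if (!is.null(se)) sprintf(" +/- %.2g", se[["p_B"]]) else ""))
  cat(" ", paste(x$members, collapse = ", "), "\n")
  if (length(x$ejected)) cat("  ejected:", paste(x$ejected, collapse = ", "), "\n")
  invisible(x)
}

#' Try to place a methyl into an existing cluster
#'
#' With the cluster's shared (k_ex, p_B) held fixed, fits only the methyl's
#' own parameters (dw and per-field R2,0) and evaluates the chi^2-ratio rule.
#'
#' @param cluster A `cpmg_cluster`.
#' @param dataset Dataset containing the methyl's profiles.
#' @param key Methyl key.
#' @param individual_fit The methyl's individual `cpmg_fit`.
#' @inheritParams fit_cluster_global
#' @return List with `accept` (logical) and `chi2_cluster` (reduced).
#' @export
try_assign_member <- function(cluster, dataset, key, individual_fit, fields,
                              schedule, bounds = default_bounds()) {
  prof <- .profile_list(dataset)[[key]]
  if (is.null(prof)) stop("no profiles for ", key, call. = FALSE)
  labels <- names(prof$fields)
  t_relax <- schedule$t_relax
  res_fn <- function(q) {
    p <- c(cluster$k_ex, cluster$p_B, q)
    mi <- list(dw = 3L, r20 = setNames(3L + seq_along(labels), labels),
               labels = labels)
    .member_res(p, prof, mi, fields, t_relax)
  }
  q0 <- c(max(individual_fit$params$dw_ppm, 2 * bounds$lower["dw_ppm"]),
          unlist(individual_fit$params$r20_by_field[labels]))
  fit <- nls.lm(par = q0, fn = res_fn,
                lower = unname(c(bounds$lower["dw_ppm"],
                                 rep(bounds$lower["r20"], length(labels)))),
                upper = unname(c(bounds$upper["dw_ppm"],
                                 rep(bounds$upper["r20"], length(labels)))),
                control = nls.lm.control(maxiter = 200))
  dof <- max(1L, .n_points(prof) - (3L + length(labels)))
  chi2_cl <- fit$deviance / dof
  list(accept = accept_member(chi2_cl, individual_fit$chi2_reduced),
       chi2_cluster = chi2_cl,
       dw_ppm = fit$par[1],
       r20_by_field = setNames(fit$par[-1], labels))
}

## --- Monte Carlo uncertainties ---------------------------------------

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Monte Carlo parameter uncertainties
#'
#' Synthetic replicate datasets are built from the best-fit curve plus
#' Gaussian noise at the per-point sigma, each replicate is refitted
#' starting from the converged parameters, and the parameter uncertainty is
#' the standard deviation over converged replicates.  Deterministic under a
#' fixed seed.  A warning is attached when more than 20% of replicates fail
#' to converge.
#'
#' @param fit A converged `cpmg_fit` (individual) or `cpmg_cluster` object.
#' @param dataset The dataset the fit was obtained from.
#' @param fields Named list of [field_context()] objects.
#' @param schedule A [cpmg_schedule()].
#' @param n_reps Number of Monte Carlo replicates (default 100).
#' @param seed Integer seed.
#' @param ... Passed on to methods.
#' @return The fit object with `param_sigmas` filled in (named: `k_ex`,
#'   `p_B`, and for individual fits `dw_ppm` and per-field `r20`; clusters
#'   also carry `dw_sigmas_by_member`).
#' @export
monte_carlo_sigmas <- function(fit, dataset, fields, schedule,
                               n_reps = 100L, seed = 1L, ...) {
  UseMethod("monte_carlo_sigmas")
}

#' @rdname monte_carlo_sigmas
#' @export
monte_carlo_sigmas.cpmg_fit <- function(fit, dataset, fields, schedule,
                                        n_reps = 100L, seed = 1L, ...) {
  if (!isTRUE(fit$converged))
    stop("Monte Carlo uncertainties need a converged fit", call. = FALSE)
  prof <- .profile_list(dataset)[[fit$key]]
  labels <- names(prof$fields)
  t_relax <- schedule$t_relax
  p_hat <- c(fit$params$k_ex, fit$params$p_B, fit$params$dw_ppm,
             unlist(fit$params$r20_by_field[labels]))
  curve <- list()
  for (fl in labels) {
    fp <- prof$fields[[fl]]
    dw_rad <- p_hat[3] * 2 * pi * fields[[fl]]$larmor_13c_mhz
    curve[[fl]] <- .bm_core(p_hat[1], p_hat[2], dw_rad,
                            p_hat[3 + match(fl, labels)], t_relax, fp$nu)
  }
  bounds <- default_bounds()
  lower <- c(bounds$lower[c("k_ex", "p_B", "dw_ppm")],
             rep(bounds$lower["r20"], length(labels)))
  upper <- c(bounds$upper[c("k_ex", "p_B", "dw_ppm")],
             rep(bounds$upper["r20"], length(labels)))
  draws <- .with_seed(seed, {
    out <- matrix(NA_real_, n_reps, length(p_hat))
    for (r in seq_len(n_reps)) {
      prof_r <- prof
      for (fl in labels) {
        fp <- prof$fields[[fl]]
        prof_r$fields[[fl]]$r2 <- curve[[fl]] + rnorm(length(fp$nu), 0, fp$sigma)
      }
      ft <- tryCatch(
        nls.lm(par = p_hat, fn = .res_exchange, prof = prof_r,
               fields = fields, labels = labels, t_relax = t_relax,
               lower = lower, upper = upper,
               control = nls.lm.control(maxiter = 150)),
        error = function(e) NULL)
      if (!is.null(ft) && ft$info %in% 1:4) out[r, ] <- ft$par
    }
    out
  })
  ok <- stats::complete.cases(draws)
  if (mean(ok) < 0.8)
    warning(sprintf("%d%% of Monte Carlo replicates failed to converge",
                    round(100 * mean(!ok))), call. = FALSE)
  sig <- apply(draws[ok, , drop = FALSE], 2, sd)
  fit$param_sigmas <- setNames(sig, c("k_ex", "p_B", "dw_ppm",
                                      paste0("r20_", labels)))
  fit$mc_n_converged <- sum(ok)
  fit
}

#' @rdname monte_carlo_sigmas
#' @export
monte_carlo_sigmas.cpmg_cluster <- function(fit, dataset, fields, schedule,
                                            n_reps = 100L, seed = 1L, ...) {
  if (length(fit$members) < 2L)
    stop("cannot resample an empty cluster", call. = FALSE)
  profs <- .profile_list(dataset)[fit$members]
  layout <- .cluster_layout(profs)
  t_relax <- schedule$t_relax
  p_hat <- numeric(layout$n_par)
  p_hat[1] <- fit$k_ex; p_hat[2] <- fit$p_B
  for (key in fit$members) {
    mi <- layout$idx[[key]]
    p_hat[mi$dw] <- fit$per_member[[key]]$dw_ppm
    for (fl in mi$labels)
      p_hat[mi$r20[[fl]]] <- fit$per_member[[key]]$r20_by_field[[fl]]
  }
  curves <- lapply(fit$members, function(key) {
    prof <- profs[[key]]; mi <- layout$idx[[key]]
    lapply(setNames(mi$labels, mi$labels), function(fl) {
      fp <- prof$fields[[fl]]
      dw_rad <- p_hat[mi$dw] * 2 * pi * fields[[fl]]$larmor_13c_mhz
      .bm_core(p_hat[1], p_hat[2], dw_rad, p_hat[mi$r20[[fl]]], t_relax, fp$nu)
    })
  })
  names(curves) <- fit$members
  bounds <- default_bounds()
  draws <- .with_seed(seed, {
    out <- matrix(NA_real_, n_reps, layout$n_par)
    for (r in seq_len(n_reps)) {
      profs_r <- profs
      for (key in fit$members) {
        for (fl in names(profs[[key]]$fields)) {
          fp <- profs[[key]]$fields[[fl]]
          profs_r[[key]]$fields[[fl]]$r2 <-
            curves[[key]][[fl]] + rnorm(length(fp$nu), 0, fp$sigma)
        }
      }
      ft <- tryCatch(
        .fit_cluster_once(profs_r, p_hat, layout, fields, t_relax, bounds),
        error = function(e) NULL)
      if (!is.null(ft) && ft$info %in% 1:4) out[r, ] <- ft$par
    }
    out
  })
  ok <- stats::complete.cases(draws)
  if (mean(ok) < 0.8)
    warning(sprintf("%d%% of Monte Carlo replicates failed to converge",
                    round(100 * mean(!ok))), call. = FALSE)
  sig <- apply(draws[ok, , drop = FALSE], 2, sd)
  fit$param_sigmas <- c(k_ex = sig[1], p_B = sig[2])
  names(fit$param_sigmas) <- c("k_ex", "p_B")
  fit$dw_sigmas_by_member <- setNames(
    vapply(fit$members, function(key) sig[layout$idx[[key]]$dw], 0),
    fit$members)
  fit$mc_n_converged <- sum(ok)
  fit
}
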