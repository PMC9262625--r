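#' Plot dispersion profiles for one methyl group
#'
#' Base-graphics plot of R2,eff versus refocusing frequency for every field
#' of one methyl, with error bars from `sigma_s` and optional fitted
#' curves.
#'
#' @param dataset Long dispersion data frame.
#' @param residue_id,methyl_id Methyl to plot.
#' @param fit Optional `cpmg_fit` (exchange model) whose curve is overlaid.
#' @param fields Named list of [field_context()]s (needed with `fit`).
#' @param schedule A [cpmg_schedule()] (needed with `fit`).
#' @param ... Passed to [plot()].
#' @return Invisibly, the plotted subset.
#' @export
plot_dispersion <- function(dataset, residue_id, methyl_id, fit = NULL,
                            fields = default_fields(),
                            schedule = default_schedule(), ...) {
  d <- collapse_duplicates(dataset)
  d <- d[d$residue_id == residue_id & d$methyl_id == methyl_id, ,
         drop = FALSE]
  if (nrow(d) == 0L) stop("no points for that methyl", call. = FALSE)
  labs <- unique(d$field_label)
  cols <- setNames(seq_along(labs), labs)
  plot(d$nu_cpmg_hz, d$r2eff_s, type = "n",
       xlab = expression(nu[CPMG] ~ (s^-1)),
       ylab = expression(R["2,eff"] ~ (s^-1)),
       main = paste0(residue_id, " (", methyl_id, ")"), ...)
  for (fl in labs) {
    dd <- d[d$field_label == fl, ]
    graphics::points(dd$nu_cpmg_hz, dd$r2eff_s, col = cols[fl], pch = 16)
    graphics::arrows(dd$nu_cpmg_hz, dd$r2eff_s - dd$sigma_s,
                     dd$nu_cpmg_hz, dd$r2eff_s + dd$sigma_s,
                     angle = 90, code = 3, length = 0.02, col = cols[fl])
    if (!is.null(fit) && fit$model == "exchange") {
      nu_fine <- seq(min(dd$nu_cpmg_hz), max(dd$nu_cpmg_hz), length.out = 80)
      nu_fine <- nu_fine[n_refocusing_pulses(nu_fine, schedule$t_relax) >= 2]
      graphics::lines(nu_fine,
                      bm_r2eff(fit$params, fields[[fl]], schedule, nu_fine),
                      col = cols[fl])
    }
  }
  graphics::legend("topright", legend = labs, col = cols, pch = 16,
                   bty = "n")
  invisible(d)
}
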