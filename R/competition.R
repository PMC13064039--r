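#' Construct a condition-tagged binding fit
#'
#' Pairs a binding fit with the experimental condition it was measured
#' under: the blank (ligand + protein alone), a Sudlow site-marker probe
#' (phenylbutazone for site I, diazepam for site II), a metal ion, or any
#' other condition. Comparative analyses operate on sets of these.
#'
#' @param condition free-text condition label (e.g. `"blank"`,
#'   `"phenylbutazone"`, `"Ca2+"`).
#' @param site_role one of `"blank"`, `"site_I_probe"`, `"site_II_probe"`,
#'   `"metal"`, `"other"`.
#' @param fit a `binding_fit` (from [fit_double_log()] or
#'   [binding_record()]).
#' @return An object of class `condition_fit`.
#' @export
condition_fit <- function(condition, site_role, fit) {
  site_role <- match.arg(site_role,
                         c("blank", "site_I_probe", "site_II_probe",
                           "metal", "other"))
  stopifnot(is.character(condition), length(condition) == 1,
            inherits(fit, "binding_fit"))
  structure(list(condition = condition, site_role = site_role, fit = fit),
            class = "condition_fit")
}

find_blank <- function(fits) {
  stopifnot(all(vapply(fits, inherits, TRUE, "condition_fit")))
  roles <- vapply(fits, function(f) f$site_role, "")
  ib <- which(roles == "blank")
  if (length(ib) == 0)
    stop("missing reference condition: exactly one blank is required")
  if (length(ib) > 1)
    stop("ambiguous reference: more than one blank condition supplied")
  ib
}

#' Assign the binding site from site-marker competition
#'
#' Compares the binding constant of the ligand measured alone (blank)
#' against its constant in the presence of saturating site markers. A probe
#' that depresses `log10 Kb` by at least `threshold` competes with the
#' ligand for its pocket, assigning the site the probe reports
#' (phenylbutazone-type probes report Sudlow site I, diazepam-type probes
#' site II). Both probes depressing gives `"both"`; neither gives
#' `"indeterminate"`. Condition order is irrelevant.
#'
#' @param fits list of [condition_fit()]s: exactly one blank plus at least
#'   one probe condition.
#' @param threshold minimum drop in `log10 Kb` (blank minus probe) that
#'   counts as displacement.
#' @return An object of class `site_call` with `assigned_site`,
#'   `delta_log_kb_by_condition` and `threshold`.
#' @examples
#' fits <- list(
#'   condition_fit("blank", "blank", binding_record(2.55)),
#'   condition_fit("phenylbutazone", "site_I_probe", binding_record(1.91)),
#'   condition_fit("diazepam", "site_II_probe", binding_record(2.50)))
#' assign_site(fits)
#' @export
assign_site <- function(fits, threshold = 0.2) {
  ib <- find_blank(fits)
  blank_lk <- fits[[ib]]$fit$log_kb
  roles <- vapply(fits, function(f) f$site_role, "")
  probe_idx <- which(roles %in% c("site_I_probe", "site_II_probe"))
  if (length(probe_idx) == 0)
    stop("no probe conditions supplied")

  delta <- vapply(fits[probe_idx], function(f) blank_lk - f$fit$log_kb, 0)
  names(delta) <- vapply(fits[probe_idx], function(f) f$condition, "")
  hit_roles <- unique(roles[probe_idx][delta >= threshold])
  sites <- sub("_probe$", "", hit_roles)
  assigned <- if (length(sites) == 0) "indeterminate"
              else if (all(c("site_I", "site_II") %in% sites)) "both"
              else sites[1]
  structure(list(assigned_site = assigned,
                 delta_log_kb_by_condition = delta,
                 threshold = threshold, blank_log_kb = blank_lk),
            class = "site_call")
}

#' @export
print.site_call <- function(x, ...) {
  cat(sprintf("Site-marker competition: assigned site = %s (threshold %.2g)\n",
              x$assigned_site, x$threshold))
  for (nm in names(x$delta_log_kb_by_condition))
    cat(sprintf("  %s: delta log10 Kb = %+.3f\n", nm,
                x$delta_log_kb_by_condition[[nm]]))
  invisible(x)
}

#' Metal-ion modulation of binding affinity
#'
#' Compares the binding constant of the ligand-protein system with and
#' without each metal ion. A metal whose `log10 Kb` exceeds the blank's by
#' at least `threshold` enhances binding; one at least `threshold` below
#' reduces it; everything in between is unchanged. The linear-scale ratio
#' `kb(metal)/kb(blank)` is reported alongside. Condition order is
#' irrelevant.
#'
#' @param fits list of [condition_fit()]s: exactly one blank plus at least
#'   one condition of role `"metal"`.
#' @param threshold minimum `|delta log10 Kb|` counting as a change.
#' @return An object of class `metal_report` with a per-metal `table`
#'   (`condition`, `delta_log_kb`, `ratio`, `label`) and `threshold`.
#' @export
metal_modulation <- function(fits, threshold = 0.15) {
  ib <- find_blank(fits)
  blank <- fits[[ib]]$fit
  roles <- vapply(fits, function(f) f$site_role, "")
  mi <- which(roles == "metal")
  if (length(mi) == 0) stop("no metal conditions supplied")

  dlog <- vapply(fits[mi], function(f) f$fit$log_kb - blank$log_kb, 0)
  ratio <- vapply(fits[mi], function(f) f$fit$kb / blank$kb, 0)
  label <- ifelse(dlog >= threshold, "enhanced",
                  ifelse(dlog <= -threshold, "reduced", "unchanged"))
  tab <- data.frame(condition = vapply(fits[mi], function(f) f$condition, ""),
                    delta_log_kb = dlog, ratio = ratio, label = label,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, threshold = threshold,
                 blank_log_kb = blank$log_kb),
            class = "metal_report")
}

#' @export
print.metal_report <- function(x, ...) {
  cat(sprintf("Metal-ion modulation (threshold %.2g on log10 Kb):\n",
              x$threshold))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
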