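# End-to-end drivers: the registration parameter sweep (pyramid levels x
# neighborhood radius) and the dose-accumulation assessment, run on one or
# more cases.

#' Run configuration
#'
#' @param cases list of [phantom_spec()]s or of `list(bundle =, field =)`
#'   case objects (field optional).
#' @param grid data frame with columns `levels` and `radius`: the sweep
#'   grid of pyramid depth x neighborhood radius.
#' @param lk base [lk_params()] whose `pyramid_levels` / `window_radius`
#'   the sweep overrides.
#' @param gamma a [gamma_params()].
#' @param inpaint an [inpaint_params()].
#' @param affine an [affine_reg_params()], or `NULL` to skip the automatic
#'   affine stage.
#' @param alpha_beta_landmark alpha/beta (Gy) for the landmark EQD2 report.
#' @param alpha_beta_oar alpha/beta (Gy) for the organ-at-risk DVH
#'   comparison.
#' @param v_cm3 DVH hot-spot volumes (cm^3).
#' @param oar name of the organ used for the DVH comparison.
#' @param seed master seed.
#' @param out_dir optional directory for a manifest + result files.
#' @return A `run_config` list.
#' @export
run_config <- function(cases = list(phantom_spec()),
                       grid = expand.grid(levels = c(2L, 3L), radius = c(2L, 3L, 4L)),
                       lk = lk_params(), gamma = gamma_params(),
                       inpaint = inpaint_params(), affine = affine_reg_params(),
                       alpha_beta_landmark = 10, alpha_beta_oar = 3,
                       v_cm3 = c(0.1, 2), oar = "bladder",
                       seed = 1L, out_dir = NULL) {
  if (nrow(grid) < 1L) stop("sweep grid must be non-empty")
  structure(list(cases = cases, grid = grid, lk = lk, gamma = gamma,
                 inpaint = inpaint, affine = affine,
                 alpha_beta_landmark = alpha_beta_landmark,
                 alpha_beta_oar = alpha_beta_oar, v_cm3 = v_cm3, oar = oar,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

resolve_case <- function(x) {
  if (inherits(x, "phantom_spec")) make_case(x)
  else x
}

# shared per-case front end: in-paint the applicator, optional affine stage.
# The affine result is carried as an initial deformation field (composite
# transform), never as a resampled volume, so the floating image is only
# interpolated once by whatever consumes the final field.
prepare_case <- function(cs, config) {
  b <- cs$bundle
  ref <- b$reference_ct
  ap <- b$masks$applicator_ref
  if (!is.null(ap) && !ap$empty)
    ref <- replace_applicator(ref, ap, config$inpaint)
  flt <- b$floating_ct
  body <- b$masks$body_ref
  t_aff <- NULL
  f_aff <- NULL
  if (!is.null(config$affine)) {
    t_aff <- affine_register(flt, ref, config$affine, body)
    f_aff <- affine_to_field(t_aff, geometry_of(ref))
  }
  list(ref = ref, flt = flt, t_aff = t_aff, f_aff = f_aff, body = body,
       landmarks = b$landmarks)
}

case_metrics <- function(ref, registered, body, landmarks, config,
                         field = NULL, transform = NULL) {
  list(lm_mm = landmark_distance(landmarks, field, transform)$mean,
       rmse_hu = rmse_within_mask(ref, registered, body),
       gamma_pct = gamma_study(ref, registered, body, config$gamma)$study_pct)
}

#' Registration parameter sweep (study 1 analogue)
#'
#' For every case and every `(pyramid levels, neighborhood radius)`
#' combination: in-paint the applicator, optionally affine-preregister,
#' run the pyramidal Lucas-Kanade registration, and score it by mean
#' landmark distance, masked HU RMSE and the study gamma score. Also
#' reports the pre-registration and after-affine baselines. Failures in a
#' sweep cell are recorded and do not stop the sweep.
#'
#' @param config a [run_config()].
#' @return List with `table` (per case x cell metrics), `baseline`
#'   (pre-registration / after-affine rows), `combined` (cell means over
#'   cases) and `optimum` (best cell: landmark distance, ties by RMSE,
#'   then gamma).
#' @export
run_study1 <- function(config = run_config()) {
  rows <- list(); base_rows <- list()
  for (ci in seq_along(config$cases)) {
    cs <- resolve_case(config$cases[[ci]])
    pc <- prepare_case(cs, config)
    m0 <- case_metrics(pc$ref, pc$flt, pc$body, pc$landmarks, config)
    base_rows[[length(base_rows) + 1L]] <-
      data.frame(case = ci, stage = "pre", lm_mm = m0$lm_mm,
                 rmse_hu = m0$rmse_hu, gamma_pct = m0$gamma_pct)
    aff_reg <- if (is.null(pc$f_aff)) pc$flt else warp_volume(pc$flt, pc$f_aff)
    ma <- case_metrics(pc$ref, aff_reg, pc$body, pc$landmarks, config,
                       field = pc$f_aff)
    base_rows[[length(base_rows) + 1L]] <-
      data.frame(case = ci, stage = "affine", lm_mm = ma$lm_mm,
                 rmse_hu = ma$rmse_hu, gamma_pct = ma$gamma_pct)
    for (gi in seq_len(nrow(config$grid))) {
      lev <- config$grid$levels[gi]; rad <- config$grid$radius[gi]
      res <- tryCatch({
        p <- config$lk
        p$pyramid_levels <- as.integer(lev)
        p$window_radius <- as.integer(rad)
        p$weight_sigma <- 2 * rad / 3
        field <- pyramid_lk_register(pc$ref, pc$flt, p, init_field = pc$f_aff)
        registered <- warp_volume(pc$flt, field)
        m <- case_metrics(pc$ref, registered, pc$body, pc$landmarks, config,
                          field = field)
        data.frame(case = ci, levels = lev, radius = rad, lm_mm = m$lm_mm,
                   rmse_hu = m$rmse_hu, gamma_pct = m$gamma_pct,
                   error = NA_character_)
      }, error = function(e)
        data.frame(case = ci, levels = lev, radius = rad, lm_mm = NA_real_,
                   rmse_hu = NA_real_, gamma_pct = NA_real_,
                   error = conditionMessage(e)))
      rows[[length(rows) + 1L]] <- res
    }
  }
  tab <- do.call(rbind, rows)
  base <- do.call(rbind, base_rows)
  comb <- stats::aggregate(tab[c("lm_mm", "rmse_hu", "gamma_pct")],
                           by = tab[c("levels", "radius")], FUN = mean)
  ok <- stats::complete.cases(comb)
  opt <- comb[ok, ][order(comb$lm_mm[ok], comb$rmse_hu[ok],
                          -comb$gamma_pct[ok]), ][1, ]
  out <- list(table = tab, baseline = base, combined = comb,
              optimum = list(levels = opt$levels, radius = opt$radius))
  maybe_write_manifest(config, out, "study1")
  out
}

#' Dose-accumulation assessment (study 2 analogue)
#'
#' Per case: register with the configured Lucas-Kanade parameters, convert
#' both course doses to EQD2, map the EBRT dose through the field into the
#' reference frame, accumulate, and report the landmark dose differences
#' (after the deformable field, after the affine-only stage, and -- when
#' the case carries one -- under the ground-truth field), plus the
#' DVH-parameter-addition vs DIR-accumulation comparison for the
#' organ-at-risk hot-spot volumes.
#'
#' @param config a [run_config()]; `config$lk` holds the (optimized)
#'   registration parameters.
#' @return List with `landmark_table` (per case mean absolute / relative
#'   EQD2 differences) and `dvh_table` (per case added vs DIR D_v values).
#' @export
run_study2 <- function(config = run_config()) {
  lm_rows <- list(); dvh_rows <- list()
  for (ci in seq_along(config$cases)) {
    cs <- resolve_case(config$cases[[ci]])
    pc <- prepare_case(cs, config)
    b <- cs$bundle
    field <- pyramid_lk_register(pc$ref, pc$flt, config$lk,
                                 init_field = pc$f_aff)
    sch_e <- fractionation_scheme(b$fractionation$ebrt$n_fractions,
                                  config$alpha_beta_landmark,
                                  b$fractionation$ebrt$total_dose_gy)
    sch_b <- fractionation_scheme(b$fractionation$brt$n_fractions,
                                  config$alpha_beta_landmark,
                                  b$fractionation$brt$total_dose_gy)
    ebrt_eq <- eqd2(b$floating_dose, sch_e)
    brt_eq <- eqd2(b$reference_dose, sch_b)
    rep_lk <- dose_difference_report(b$landmarks, ebrt_eq, brt_eq, field)
    aff_field <- if (is.null(pc$f_aff)) zero_field(geometry_of(pc$ref))
                 else pc$f_aff
    rep_aff <- dose_difference_report(b$landmarks, ebrt_eq, brt_eq, aff_field)
    row <- data.frame(case = ci,
                      lk_abs_gy = rep_lk$summary$mean_abs_diff_gy,
                      lk_rel_pct = rep_lk$summary$mean_rel_diff_pct,
                      affine_abs_gy = rep_aff$summary$mean_abs_diff_gy,
                      affine_rel_pct = rep_aff$summary$mean_rel_diff_pct,
                      true_abs_gy = NA_real_, true_rel_pct = NA_real_)
    if (!is.null(cs$field)) {
      rep_true <- dose_difference_report(b$landmarks,
                                         eqd2(b$floating_dose, sch_e),
                                         brt_eq, cs$field)
      row$true_abs_gy <- rep_true$summary$mean_abs_diff_gy
      row$true_rel_pct <- rep_true$summary$mean_rel_diff_pct
    }
    lm_rows[[ci]] <- row

    oe <- fractionation_scheme(b$fractionation$ebrt$n_fractions,
                               config$alpha_beta_oar,
                               b$fractionation$ebrt$total_dose_gy)
    ob <- fractionation_scheme(b$fractionation$brt$n_fractions,
                               config$alpha_beta_oar,
                               b$fractionation$brt$total_dose_gy)
    mref <- b$masks[[paste0(config$oar, "_ref")]]
    mflt <- b$masks[[paste0(config$oar, "_flt")]]
    if (!is.null(mref)) {
      cmp <- compare_accumulation(eqd2(b$floating_dose, oe),
                                  eqd2(b$reference_dose, ob),
                                  field, mref, config$v_cm3,
                                  mask_floating = mflt)
      cmp$case <- ci
      dvh_rows[[length(dvh_rows) + 1L]] <- cmp
    }
  }
  out <- list(landmark_table = do.call(rbind, lm_rows),
              dvh_table = if (length(dvh_rows)) do.call(rbind, dvh_rows) else NULL)
  maybe_write_manifest(config, out, "study2")
  out
}

maybe_write_manifest <- function(config, result, what) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    what = what,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("ctdosemap")),
    grid = config$grid,
    lk = unclass(config$lk),
    gamma = unclass(config$gamma),
    inpaint = unclass(config$inpaint),
    n_cases = length(config$cases))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, paste0(what, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  for (nm in names(result)) {
    if (is.data.frame(result[[nm]]))
      utils::write.csv(result[[nm]],
                       file.path(config$out_dir, paste0(what, "_", nm, ".csv")),
                       row.names = FALSE)
  }
  invisible(NULL)
}
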