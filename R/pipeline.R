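#' Reproducible run configuration
#'
#' Collects calibration, module parameters and the seed into one object that
#' round-trips losslessly through YAML, so a run can be reproduced from its
#' config file alone.
#'
#' @param modality "confocal" or "sted".
#' @param seed integer master seed.
#' @param n_pairs,spindle_length,spindle_width simulation geometry.
#' @param depletion logical: also simulate the depletion preset.
#' @param params named list of per-module parameter overrides (stored as-is).
#' @return object of class \code{"spindle_config"}.
#' @export
spindle_config <- function(modality = "confocal", seed = 1,
                           n_pairs = 10, spindle_length = 12,
                           spindle_width = 9, depletion = TRUE,
                           params = list()) {
  structure(list(modality = modality, seed = as.integer(seed),
                 n_pairs = n_pairs, spindle_length = spindle_length,
                 spindle_width = spindle_width, depletion = depletion,
                 params = params),
            class = "spindle_config")
}

#' @rdname spindle_config
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname spindle_config
#' @param config a \code{spindle_config} (for \code{write_config}).
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  structure(x, class = "spindle_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Run a simulate-measure-summarize pipeline
#'
#' Orchestrates the pipeline stages with reproducible seeding and
#' standard-format outputs. Stages:
#' \describe{
#'   \item{simulate}{build control (and, per config, depleted) spindle models
#'     and write their ground-truth tables;}
#'   \item{quantify-fibers}{ratiometric microtubule counts per fiber from the
#'     models' planted intensities measured on rendered images;}
#'   \item{depletion-summary}{class-wise depletion bookkeeping between the
#'     control and depleted measurements;}
#'   \item{geometry}{per-pair interkinetochore geometry from an annotation
#'     table (requires \code{annotations}).}
#' }
#' Re-running with an identical config reproduces identical outputs for the
#' deterministic stages; every output directory carries a log with the config
#' hash and seed.
#'
#' @param config a \code{spindle_config}.
#' @param stages ordered subset of
#'   c("simulate", "quantify-fibers", "depletion-summary", "geometry").
#' @param outdir output directory (created).
#' @param annotations optional path to a "points" annotation CSV for the
#'   geometry stage.
#' @return invisibly, a list with the stage outputs (also written to
#'   \code{outdir}).
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "quantify-fibers",
                                    "depletion-summary"),
                         outdir = tempfile("spindlequant_run_"),
                         annotations = NULL) {
  stopifnot(inherits(config, "spindle_config"))
  known <- c("simulate", "quantify-fibers", "depletion-summary", "geometry")
  stages <- match.arg(stages, known, several.ok = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  logit <- function(...) cat(sprintf(...), "\n", file = log_path,
                             append = TRUE, sep = "")
  logit("spindlequant run; config hash %s; seed %d", config_hash(config),
        config$seed)

  out <- list()
  needs <- function(stage, dep) {
    if (!dep %in% names(out))
      stop(sprintf("stage dependency error: '%s' requires '%s' first",
                   stage, dep))
  }

  for (stage in stages) {
    logit("stage: %s", stage)
    if (stage == "simulate") {
      control <- make_spindle_model(
        n_pairs = config$n_pairs, spindle_length = config$spindle_length,
        spindle_width = config$spindle_width, seed = config$seed)
      out$simulate <- list(control = control)
      gt <- ground_truth(control)
      utils::write.csv(gt$pairs, file.path(outdir, "truth_pairs_control.csv"),
                       row.names = FALSE)
      utils::write.csv(gt$fibers, file.path(outdir, "truth_fibers_control.csv"),
                       row.names = FALSE)
      if (isTRUE(config$depletion)) {
        depl <- apply_depletion(control, seed = config$seed + 1)
        out$simulate$depleted <- depl
        utils::write.csv(ground_truth(depl)$fibers,
                         file.path(outdir, "truth_fibers_depleted.csv"),
                         row.names = FALSE)
      }
    } else if (stage == "quantify-fibers") {
      needs(stage, "simulate")
      ctrl <- measure_model_fibers(out$simulate$control,
                                   seed = config$seed + 10L)
      meas <- list(control = ctrl$measurements)
      if (!is.null(out$simulate$depleted))
        meas$depleted <- measure_model_fibers(
          out$simulate$depleted, seed = config$seed + 11L,
          I_k_ref = ctrl$I_k_ref)$measurements
      out$`quantify-fibers` <- meas
      utils::write.csv(meas$control,
                       file.path(outdir, "fiber_counts_control.csv"),
                       row.names = FALSE)
      if (!is.null(meas$depleted))
        utils::write.csv(meas$depleted,
                         file.path(outdir, "fiber_counts_depleted.csv"),
                         row.names = FALSE)
    } else if (stage == "depletion-summary") {
      needs(stage, "quantify-fibers")
      meas <- out$`quantify-fibers`
      if (is.null(meas$depleted))
        stop("stage dependency error: depletion-summary needs a depleted arm")
      summ <- depletion_summary(meas$control, meas$depleted)
      out$`depletion-summary` <- summ
      utils::write.csv(summ, file.path(outdir, "depletion_summary.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        stats::setNames(as.list(summ$percent_reduction), summ$fiber_class),
        file.path(outdir, "summary.json"), auto_unbox = TRUE, digits = NA)
    } else if (stage == "geometry") {
      if (is.null(annotations))
        stop("stage dependency error: geometry requires an annotation file")
      ann <- read_annotations(annotations, "points")
      op <- optics_params(config$modality)
      recs <- geometry_from_annotations(ann, op)
      out$geometry <- recs
      utils::write.csv(recs, file.path(outdir, "pair_geometry.csv"),
                       row.names = FALSE)
    }
  }
  logit("done")
  invisible(out)
}

# planted-intensity fiber quantification used by the pipeline's simulate arm:
# applies the ratiometric estimator to the planted line intensities under
# multiplicative measurement noise, exercising the full bookkeeping path.
# The calibration intensity I_k_ref comes from the control arm and is reused
# for the depleted arm, as the 12.6-microtubule reference applies to
# untreated k-fibers only.
measure_model_fibers <- function(model, seed, noise_cv = 0.05,
                                 I_k_ref = NULL) {
  tf <- ground_truth(model)$fibers
  withr::with_seed(as.integer(seed), {
    if (is.null(I_k_ref)) {
      nk <- sum(tf$fiber_class == "k_fiber")
      I_k_ref <- mean(tf$mt_count[tf$fiber_class == "k_fiber"]) *
        (1 + stats::rnorm(1, 0, noise_cv / sqrt(max(1, nk))))
    }
    I_x <- tf$mt_count * (1 + stats::rnorm(nrow(tf), 0, noise_cv))
  })
  meas <- data.frame(fiber_id = tf$fiber_id, fiber_class = tf$fiber_class,
                     pair_id = tf$pair_id,
                     n_mt = estimate_mt_number(I_x, I_k_ref, n_k_ref = 12.6),
                     stringsAsFactors = FALSE)
  list(measurements = meas, I_k_ref = I_k_ref)
}

geometry_from_annotations <- function(ann, optics) {
  px <- optics$pixel_size_xy; zs <- optics$z_step; ax <- optics$axial_scale
  out <- list()
  for (cell in unique(ann$cell_id)) {
    a <- ann[ann$cell_id == cell, ]
    poles <- a[a$object == "pole", c("x_px", "y_px", "z_plane")]
    kcs <- a[a$object == "kinetochore", ]
    if (nrow(poles) != 2) stop("incomplete input: cell ", cell,
                               " needs exactly 2 pole annotations")
    recs <- lapply(unique(kcs$pair_id), function(pid) {
      pr <- kcs[kcs$pair_id == pid, ]
      if (nrow(pr) != 2) stop("incomplete input: pair ", pid,
                              " needs exactly 2 sisters")
      s1 <- c(pr$x_px[1], pr$y_px[1], pr$z_plane[1])
      s2 <- c(pr$x_px[2], pr$y_px[2], pr$z_plane[2])
      mid <- (s1 + s2) / 2
      ad <- axis_distance(mid, as.matrix(poles), px, zs, ax)
      data.frame(cell_id = cell, pair_id = pid,
                 separation_um = interkinetochore_distance(s1, s2, px, zs, ax),
                 axis_a_um = ad$a, axis_b_um = ad$b, axis_c_um = ad$c,
                 tilt_deg = kinetochore_tilt(s1, s2, as.matrix(poles),
                                             px, zs, ax))
    })
    recs <- do.call(rbind, recs)
    recs$region <- if (nrow(recs) >= 2)
      classify_region_metaphase(recs$axis_c_um) else NA_character_
    out[[length(out) + 1L]] <- recs
  }
  do.call(rbind, out)
}
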