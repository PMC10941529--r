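#' Default shape-parameter populations
#'
#' Population means and standard deviations used to draw per-specimen true
#' contour parameters for the two cartilage types (glenoid and
#' acromioclavicular). The defaults are anchored to published cadaveric
#' summary values so synthetic cohorts resemble real shoulders; they seed
#' realism only and can be overridden in [study_config()].
#'
#' @return A tibble with columns `cartilage_type`, `parameter`, `unit`,
#'   `mean`, `sd`.
#' @export
default_parameter_populations <- function() {
  params <- c("x", "y", "z", "alpha", "beta", "gamma", "l1", "l2", "r")
  units <- c("mm", "mm", "mm", "deg", "deg", "deg", "mm", "mm", "mm")
  tibble::tibble(
    cartilage_type = rep(c("glenoid", "acromioclavicular"), each = 9),
    parameter = rep(params, 2),
    unit = rep(units, 2),
    mean = c(31.8, -17.7, -16.6, 0.9, 10.4, -93.8, 28.8, 20.4, 38.1,
             0.1, -6.9, 134.9, 21.9, 39.0, -6.0, 20.4, 13.0, 18.3),
    sd = c(3.1, 3.4, 6.6, 6.2, 3.4, 6.6, 1.1, 1.2, 5.5,
           2.7, 1.4, 7.9, 13.8, 11.6, 12.5, 3.2, 1.2, 9.9)
  )
}

#' Synthetic-study configuration
#'
#' Defines the full design of a simulated digitalisation study: cohort size
#' and laterality split, cartilage types, numbers of operators and repeated
#' digitalisations, sampling density along the contour, the true-parameter
#' populations, and the hierarchical noise levels. Given a seed the
#' configuration fully determines every generated object.
#'
#' The default design mirrors a typical cadaveric repeatability study: 10
#' specimens (5 left, 5 right), two cartilage types, 3 operators performing 3
#' consecutive digitalisations each, and about 350 stylus samples per contour
#' (roughly 35 s of digitalisation at 10 Hz).
#'
#' @param seed Integer seed (mandatory).
#' @param n_specimens Number of specimens (default 10; lateralities alternate
#'   so even counts split half left / half right).
#' @param cartilage_types Subset of `c("glenoid", "acromioclavicular")`.
#' @param n_operators,n_digitalisations Crossed design sizes (defaults 3, 3).
#' @param points_per_contour Stylus samples per digitalised contour
#'   (default 350; rounded up to an even count).
#' @param populations Parameter population tibble as in
#'   [default_parameter_populations()].
#' @param sigma_operator SD of the operator bias, drawn once per operator x
#'   parameter x cartilage type (default 0.5 parameter units).
#' @param sigma_digitalisation SD of the digitalisation (trial) effect, drawn
#'   once per digitalisation index x parameter x cartilage type
#'   (default 0.3).
#' @param sigma_residual SD of the cell-level residual in the analytic
#'   measurement table (default 0.05, emulating the small fit-induced
#'   scatter the empirical route produces at the default sampling density).
#' @param sigma_point Isotropic per-point jitter of the stylus samples, mm
#'   (default 0.2).
#' @param landmark_noise_mm Per-specimen anatomical variation applied to the
#'   landmark template, mm (default 2).
#' @return An object of class `study_config`.
#' @export
study_config <- function(seed,
                         n_specimens = 10,
                         cartilage_types = c("glenoid", "acromioclavicular"),
                         n_operators = 3,
                         n_digitalisations = 3,
                         points_per_contour = 350,
                         populations = default_parameter_populations(),
                         sigma_operator = 0.5,
                         sigma_digitalisation = 0.3,
                         sigma_residual = 0.05,
                         sigma_point = 0.2,
                         landmark_noise_mm = 2) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    abort_contract("`seed` is mandatory in a study configuration.")
  }
  cartilage_types <- match.arg(cartilage_types,
                               c("glenoid", "acromioclavicular"),
                               several.ok = TRUE)
  counts <- c(n_specimens, n_operators, n_digitalisations, points_per_contour)
  if (any(counts < 1)) abort_contract("Design counts must be at least 1.")
  sds <- c(sigma_operator, sigma_digitalisation, sigma_residual, sigma_point,
           landmark_noise_mm, populations$sd)
  if (any(sds < 0)) abort_contract("All noise SDs must be non-negative.")
  structure(
    list(seed = as.integer(seed), n_specimens = as.integer(n_specimens),
         cartilage_types = cartilage_types,
         n_operators = as.integer(n_operators),
         n_digitalisations = as.integer(n_digitalisations),
         points_per_contour = as.integer(points_per_contour),
         populations = populations,
         sigma_operator = sigma_operator,
         sigma_digitalisation = sigma_digitalisation,
         sigma_residual = sigma_residual,
         sigma_point = sigma_point,
         landmark_noise_mm = landmark_noise_mm),
    class = "study_config"
  )
}

# Canonicalise drawn Cardan angles to the sign conventions recoverable by
# parametrise_contour().
canonical_angles <- function(alpha, beta, gamma) {
  R <- canonical_contour_rotation(cardan_to_rotation(c(alpha, beta, gamma)))
  a <- rotation_to_cardan(R)
  c(alpha = a[["alpha"]], beta = a[["beta"]], gamma = a[["gamma"]])
}

#' Draw per-specimen true contour parameters
#'
#' Independent normal draws per specimen and cartilage type from the
#' configured populations. Draws are redrawn until geometrically consistent
#' (`l1 > l2 > 0` and `r >= l1/2`, so the curvature sphere can accommodate
#' the major-axis arc), and the drawn orientation is canonicalised to the
#' axis-sign conventions recoverable from data.
#'
#' @param config A [study_config()].
#' @param seed Seed for the draws; defaults to `config$seed`. Use `NULL` to
#'   continue from the current RNG state.
#' @return A tibble: `specimen_id`, `laterality`, `cartilage_type`,
#'   `parameter`, `unit`, `true_value`.
#' @export
sample_true_parameters <- function(config, seed = config$seed) {
  with_seed(seed, {
    spec_ids <- sprintf("S%02d", seq_len(config$n_specimens))
    laterality <- rep(c("right", "left"), length.out = config$n_specimens)
    grid <- tidyr::expand_grid(specimen_id = spec_ids,
                               cartilage_type = config$cartilage_types)
    rows <- purrr::pmap(grid, function(specimen_id, cartilage_type) {
      pop <- config$populations[
        config$populations$cartilage_type == cartilage_type, , drop = FALSE]
      draw_one <- function() {
        v <- stats::rnorm(nrow(pop), pop$mean, pop$sd)
        names(v) <- pop$parameter
        v
      }
      v <- draw_one()
      tries <- 0
      while ((v[["l2"]] <= 1 || v[["l1"]] <= v[["l2"]] ||
              v[["r"]] < v[["l1"]] / 2 + 0.5) && tries < 1000) {
        v <- draw_one()
        tries <- tries + 1
      }
      if (tries >= 1000) {
        abort_contract("Could not draw geometrically consistent parameters; check the populations.")
      }
      ang <- canonical_angles(v[["alpha"]], v[["beta"]], v[["gamma"]])
      v[c("alpha", "beta", "gamma")] <- ang
      tibble::tibble(
        specimen_id = specimen_id,
        laterality = laterality[match(specimen_id, spec_ids)],
        cartilage_type = cartilage_type,
        parameter = pop$parameter, unit = pop$unit,
        true_value = unname(v)
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Generate a stylus-sampled contour point cloud
#'
#' The forward model inverse to [parametrise_contour()]: points are sampled
#' along the ellipse perimeter in antipodal pairs, lifted onto the sphere of
#' radius `r` tangent to the ellipse plane (curvature along the major-axis
#' arc, so the minor-axis projection sees a circular arc of radius `r`),
#' re-centred so the cloud centroid sits at the requested position, posed by
#' the requested position and orientation in the bone frame, and jittered
#' isotropically. Left-sided clouds are mirrored (medio-lateral coordinate
#' negated) as a left-side digitiser would record them.
#'
#' @param params Named list or one-row data frame with `x`, `y`, `z` (mm),
#'   `alpha`, `beta`, `gamma` (deg), `l1`, `l2`, `r` (mm). `r >= l1/2` is
#'   required so the sphere accommodates the major-axis arc.
#' @param n_points Number of stylus samples (>= 8; rounded up to even).
#' @param sigma_point Isotropic jitter SD, mm.
#' @param laterality `"right"` or `"left"`.
#' @param seed Optional seed (`NULL`: current RNG state).
#' @return A tibble of `x`, `y`, `z` points in the bone frame (mm).
#' @export
generate_contour_cloud <- function(params, n_points = 350, sigma_point = 0.2,
                                   laterality = c("right", "left"),
                                   seed = NULL) {
  laterality <- match.arg(laterality)
  p <- as.list(params)
  need <- c("x", "y", "z", "alpha", "beta", "gamma", "l1", "l2", "r")
  missing <- setdiff(need, names(p))
  if (length(missing) > 0) {
    abort_contract(sprintf("`params` is missing: %s.",
                           paste(missing, collapse = ", ")))
  }
  a <- p$l1 / 2; b <- p$l2 / 2; r <- p$r
  if (!(a >= b && b > 0)) abort_contract("Need l1 >= l2 > 0.")
  if (r < a) {
    abort_degenerate("`r` must be at least l1/2 so the curvature sphere accommodates the ellipse.")
  }
  if (n_points < 8) abort_contract("A contour cloud needs at least 8 points.")
  with_seed(seed, {
    half <- ceiling(n_points / 2)
    t0 <- stats::runif(half, 0, pi)
    t <- c(t0, t0 + pi)            # antipodal pairs balance the lift
    zlift <- sqrt(r^2 - (a * cos(t))^2) - r
    local <- cbind(a * cos(t), b * sin(t), zlift - mean(zlift))
    R <- cardan_to_rotation(c(p$alpha, p$beta, p$gamma))
    world <- sweep(local %*% t(R), 2, c(p$x, p$y, p$z), "+")
    if (sigma_point > 0) {
      world <- world + matrix(stats::rnorm(length(world), 0, sigma_point),
                              ncol = 3)
    }
    mirror_to_right(xyz_tibble(world), laterality)
  })
}

study_units <- function() {
  c(x = "mm", y = "mm", z = "mm", alpha = "deg", beta = "deg", gamma = "deg",
    l1 = "mm", l2 = "mm", r = "mm")
}

# Landmark templates (right side, mm) in a world frame whose +x is anterior.
landmark_template <- function(bone) {
  if (bone == "scapula") {
    list(SAA = c(0, 0, 0), SRS = c(-8, -6, -95), SIA = c(-10, -130, -85))
  } else {
    list(CSJ = c(0, 0, 0), CAJ = c(4, 6, 140), CAS = c(18, -6, 8),
         CSC = c(8, -2, 4))
  }
}

#' Generate a complete synthetic digitalisation study
#'
#' Emulates the full crossed protocol: per-specimen true contour parameters,
#' per-specimen anatomical landmark sets, operator biases (one draw per
#' operator x parameter x cartilage type), digitalisation (trial) effects
#' (one draw per digitalisation index x parameter x cartilage type), and the
#' balanced long-format measurement table
#' `value = truth + operator bias + digitalisation effect + residual`.
#' The per-cell parameters before the residual are stored so raw point
#' clouds can alternatively be generated and pushed through the real
#' parametrisation pipeline (see [empirical_measurement_table()]).
#'
#' @param config A [study_config()].
#' @return An object of class `synthetic_study`: `config`, `specimens`,
#'   `landmarks` (named list of [landmark_set()]s per specimen),
#'   `truth`, `cell_parameters` and `measurement_table` tibbles.
#' @export
generate_study <- function(config) {
  if (!inherits(config, "study_config")) {
    abort_contract("`config` must come from study_config().")
  }
  with_seed(config$seed, {
    truth <- sample_true_parameters(config, seed = NULL)
    specimens <- dplyr::distinct(truth, .data$specimen_id, .data$laterality)

    lms <- lapply(seq_len(nrow(specimens)), function(i) {
      side <- specimens$laterality[i]
      pts <- c(landmark_template("scapula"), landmark_template("clavicle"))
      base <- tibble::tibble(
        id = names(pts),
        x = vapply(pts, `[`, 0, 1),
        y = vapply(pts, `[`, 0, 2),
        z = vapply(pts, `[`, 0, 3) * (if (side == "left") -1 else 1)
      )
      for (try in 1:100) {
        tb <- base
        tb$x <- tb$x + stats::rnorm(nrow(tb), 0, config$landmark_noise_mm)
        tb$y <- tb$y + stats::rnorm(nrow(tb), 0, config$landmark_noise_mm)
        tb$z <- tb$z + stats::rnorm(nrow(tb), 0, config$landmark_noise_mm)
        out <- tryCatch(landmark_set(tb, side), error = function(e) NULL)
        if (!is.null(out)) return(out)
      }
      abort_contract("Landmark noise too large for the anatomical template.")
    })
    names(lms) <- specimens$specimen_id

    params <- unique(config$populations$parameter)
    ops <- sprintf("OP%d", seq_len(config$n_operators))
    digs <- seq_len(config$n_digitalisations)

    bias_grid <- tidyr::expand_grid(
      cartilage_type = config$cartilage_types, operator_id = ops,
      parameter = params
    )
    bias_grid$operator_bias <-
      stats::rnorm(nrow(bias_grid), 0, config$sigma_operator)
    dig_grid <- tidyr::expand_grid(
      cartilage_type = config$cartilage_types, digitalisation = digs,
      parameter = params
    )
    dig_grid$digitalisation_effect <-
      stats::rnorm(nrow(dig_grid), 0, config$sigma_digitalisation)

    cells <- truth |>
      tidyr::expand_grid(operator_id = ops, digitalisation = digs) |>
      dplyr::left_join(bias_grid, by = c("cartilage_type", "operator_id",
                                         "parameter")) |>
      dplyr::left_join(dig_grid, by = c("cartilage_type", "digitalisation",
                                        "parameter")) |>
      dplyr::mutate(
        cartilage_id = paste(.data$specimen_id, .data$cartilage_type, sep = "_"),
        cell_value = .data$true_value + .data$operator_bias +
          .data$digitalisation_effect
      )
    cells$residual <- stats::rnorm(nrow(cells), 0, config$sigma_residual)
    cells$value <- cells$cell_value + cells$residual

    measurement_table <- cells |>
      dplyr::transmute(
        cartilage_id = .data$cartilage_id, side = .data$laterality,
        cartilage_type = .data$cartilage_type,
        operator_id = .data$operator_id,
        digitalisation = .data$digitalisation,
        parameter = .data$parameter, value = .data$value, unit = .data$unit
      )

    structure(
      list(config = config, specimens = specimens, landmarks = lms,
           truth = truth, cell_parameters = cells,
           measurement_table = measurement_table),
      class = "synthetic_study"
    )
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> %d specimens x %s x %d operators x %d digitalisations (seed %d)\n",
    x$config$n_specimens, paste(x$config$cartilage_types, collapse = "+"),
    x$config$n_operators, x$config$n_digitalisations, x$config$seed
  ))
  invisible(x)
}

#' Measurement table via the real parametrisation pipeline
#'
#' The empirical route to a measurement table: for every specimen x
#' cartilage type x operator x digitalisation cell, generates a stylus point
#' cloud from the cell's perturbed parameters (truth + operator bias +
#' digitalisation effect) and recovers the nine parameters by running
#' [parametrise_contour()]. The residual variance then arises from point
#' jitter through the fits rather than being drawn, which is exactly what a
#' real study would see.
#'
#' @param study A [generate_study()] result.
#' @param seed Seed for cloud generation (default `config$seed + 1`).
#' @param n_points Points per cloud (default from the config).
#' @return A long measurement table like `study$measurement_table`.
#' @export
empirical_measurement_table <- function(study, seed = study$config$seed + 1,
                                        n_points = study$config$points_per_contour) {
  cfg <- study$config
  wide <- study$cell_parameters |>
    dplyr::select(dplyr::all_of(c(
      "cartilage_id", "specimen_id", "laterality", "cartilage_type",
      "operator_id", "digitalisation", "parameter", "cell_value"
    ))) |>
    tidyr::pivot_wider(names_from = "parameter", values_from = "cell_value")
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(wide)), function(i) {
      w <- wide[i, ]
      pars <- as.list(w[c("x", "y", "z", "alpha", "beta", "gamma",
                          "l1", "l2", "r")])
      # keep the perturbed cell geometrically admissible
      pars$l2 <- max(min(pars$l2, pars$l1 - 0.1), 1)
      pars$r <- max(pars$r, pars$l1 / 2 + 0.5)
      ang <- canonical_angles(pars$alpha, pars$beta, pars$gamma)
      pars[c("alpha", "beta", "gamma")] <- as.list(unname(ang))
      cloud <- generate_contour_cloud(
        pars, n_points = n_points, sigma_point = cfg$sigma_point,
        laterality = w$laterality, seed = NULL
      )
      cp <- parametrise_contour(cloud, laterality = w$laterality)
      est <- tidy(cp)
      tibble::tibble(
        cartilage_id = w$cartilage_id, side = w$laterality,
        cartilage_type = w$cartilage_type, operator_id = w$operator_id,
        digitalisation = w$digitalisation,
        parameter = names(study_units()),
        value = unlist(est[1, names(study_units())], use.names = FALSE),
        unit = unname(study_units())
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Default marker-instrumented stylus model
#'
#' A synthetic stylus body: `n_markers` fiducial markers distributed over a
#' sphere of radius `body_radius_mm` around the body origin (emulating the
#' faces of a marker-carrying double dodecahedron, so several markers face
#' any camera direction) and a tip offset along the stylus shaft.
#'
#' @param n_markers Number of markers (default 12).
#' @param tip_offset Tip position in the body frame, mm
#'   (default `c(0, 0, 120)`).
#' @param body_radius_mm Marker distance from the body origin (default 40).
#' @param seed Seed for the marker layout (default 42).
#' @return A [stylus_model()].
#' @export
default_stylus_model <- function(n_markers = 12, tip_offset = c(0, 0, 120),
                                 body_radius_mm = 40, seed = 42) {
  with_seed(seed, {
    markers <- lapply(seq_len(n_markers), function(i) {
      dir <- normalize(stats::rnorm(3))
      rigid_frame(body_radius_mm * dir, random_rotation())
    })
    names(markers) <- sprintf("M%02d", seq_len(n_markers))
    stylus_model(markers, tip_offset)
  })
}

#' Simulate a marker-pose stream for a tip path
#'
#' Generates per-frame fiducial-marker observations consistent with a stylus
#' body whose tip follows the given path. The body orientation wobbles
#' smoothly about a base rotation (a static tool would make the tip offset
#' unobservable), marker poses are perturbed by rotational noise and
#' anisotropic translational noise (the depth axis of a monocular camera is
#' the least constrained), and markers drop out independently at a
#' configured rate. Frames losing all markers are emitted as gap rows.
#'
#' @param tip_path Data frame with `time`, `x`, `y`, `z` (camera frame, mm).
#' @param model A [stylus_model()].
#' @param rot_noise_deg Rotational noise SD per marker, degrees (default 0).
#' @param trans_noise_mm Length-3 translational noise SD per camera axis, mm
#'   (default `c(0.1, 0.1, 0.3)`: lateral, vertical, optical/depth).
#' @param dropout_rate Per-marker-per-frame dropout probability (default 0).
#' @param wobble_deg Amplitude of the smooth orientation wobble (default 25).
#' @param seed Optional seed.
#' @return A tibble: `time`, `marker_id`, `tx`, `ty`, `tz`, `qw`, `qx`,
#'   `qy`, `qz` (gap rows have `NA` marker_id and pose).
#' @export
generate_marker_stream <- function(tip_path, model,
                                   rot_noise_deg = 0,
                                   trans_noise_mm = c(0.1, 0.1, 0.3),
                                   dropout_rate = 0,
                                   wobble_deg = 25,
                                   seed = NULL) {
  m <- as_xyz_matrix(tip_path, arg = "tip_path")
  times <- tip_path$time %||% seq_len(nrow(m)) / 10
  with_seed(seed, {
    axis <- normalize(stats::rnorm(3))
    base <- random_rotation()
    phases <- seq(0, 2 * pi, length.out = nrow(m))
    frames <- lapply(seq_len(nrow(m)), function(i) {
      ang <- deg2rad(wobble_deg * sin(phases[i]))
      K <- rbind(c(0, -axis[3], axis[2]), c(axis[3], 0, -axis[1]),
                 c(-axis[2], axis[1], 0))
      W <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
      R <- base %*% W
      origin <- m[i, ] - as.numeric(R %*% model$tip_offset)
      rigid_frame(origin, R)
    })
    rows <- lapply(seq_len(nrow(m)), function(i) {
      body <- frames[[i]]
      kept <- list()
      for (id in names(model$markers)) {
        if (dropout_rate > 0 && stats::runif(1) < dropout_rate) next
        pose <- frame_compose(body, model$markers[[id]])
        R <- pose$axes
        if (rot_noise_deg > 0) {
          nax <- normalize(stats::rnorm(3))
          nang <- deg2rad(stats::rnorm(1, 0, rot_noise_deg))
          K <- rbind(c(0, -nax[3], nax[2]), c(nax[3], 0, -nax[1]),
                     c(-nax[2], nax[1], 0))
          R <- (diag(3) + sin(nang) * K + (1 - cos(nang)) * (K %*% K)) %*% R
        }
        tr <- pose$origin + stats::rnorm(3, 0, trans_noise_mm)
        q <- rotation_to_quat(R)
        kept[[id]] <- tibble::tibble(
          time = times[i], marker_id = id, tx = tr[1], ty = tr[2], tz = tr[3],
          qw = q[1], qx = q[2], qy = q[3], qz = q[4]
        )
      }
      if (length(kept) == 0) {
        tibble::tibble(time = times[i], marker_id = NA_character_,
                       tx = NA_real_, ty = NA_real_, tz = NA_real_,
                       qw = NA_real_, qx = NA_real_, qy = NA_real_,
                       qz = NA_real_)
      } else {
        dplyr::bind_rows(kept)
      }
    })
    dplyr::bind_rows(rows)
  })
}

#' Synthetic pivoting motion for tip calibration
#'
#' Generates body poses rotating about a fixed pivot point with the tip in
#' contact: `t_i = pivot - R_i tip_offset (+ noise)`. Rotations are drawn as
#' random tilts up to `max_tilt_deg` about random axes, giving the
#' rotational diversity pivot calibration needs.
#'
#' @param tip_offset True tip offset in the body frame, mm.
#' @param pivot_point Fixed pivot location in the camera frame, mm.
#' @param n_poses Number of poses (default 60).
#' @param max_tilt_deg Maximum tilt from a reference orientation (default 30).
#' @param trans_noise_mm Translational noise SD, mm (default 0).
#' @param seed Optional seed.
#' @return A list of [rigid_frame()] body poses.
#' @export
generate_pivot_poses <- function(tip_offset, pivot_point = c(0, 0, 500),
                                 n_poses = 60, max_tilt_deg = 30,
                                 trans_noise_mm = 0, seed = NULL) {
  with_seed(seed, {
    lapply(seq_len(n_poses), function(i) {
      axis <- normalize(stats::rnorm(3))
      ang <- deg2rad(stats::runif(1, -max_tilt_deg, max_tilt_deg))
      K <- rbind(c(0, -axis[3], axis[2]), c(axis[3], 0, -axis[1]),
                 c(-axis[2], axis[1], 0))
      R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
      origin <- pivot_point - as.numeric(R %*% tip_offset)
      if (trans_noise_mm > 0) {
        origin <- origin + stats::rnorm(3, 0, trans_noise_mm)
      }
      rigid_frame(origin, R)
    })
  })
}
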