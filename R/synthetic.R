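# Synthetic vertebra/implant scenes with known ground truth. A canonical
# template (landmarks within a ~30 mm box, Toy-breed scale) carries C1 and C2
# anatomical landmarks, one implant per catalog site constructed to prescribed
# projected angles, and four safety points per implant at prescribed
# perpendicular offsets; each case is then posed by a random rigid transform.
# Gaussian landmark noise emulates operator placement variability.

#' Specification of a synthetic scene
#'
#' @param n_cases number of cases (virtual dogs); default 12, the size of the
#'   validation sample.
#' @param true_proj_angles data frame with columns `site`, `sagittal`,
#'   `dorsal` (degrees, |angle| < 90); defaults to the catalog's per-site
#'   default angles.
#' @param implant_length implant length in mm (default 10, a plausible
#'   Toy-breed corridor length).
#' @param safety_offsets perpendicular safety-point offsets in mm; scalar or
#'   length 4 `(S1, S2, S3, S4)` (default 2 mm).
#' @param implant_radius implant radius in mm (default 0.75, i.e. a 1.5 mm
#'   implant diameter).
#' @param landmark_noise_sd isotropic landmark placement noise SD in mm
#'   (default 0.3125, half a 0.625 mm CT slice thickness).
#' @param max_translation rigid-pose translation range, uniform in
#'   `[-max_translation, max_translation]` mm per axis (default 100).
#' @param random_pose pose each case with a random rigid transform (default
#'   `TRUE`); `FALSE` keeps the canonical template pose.
#' @param seed integer seed for scene generation.
#' @param catalog an [implant_site_catalog()].
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(n_cases = 12L,
                       true_proj_angles = NULL,
                       implant_length = 10,
                       safety_offsets = 2,
                       implant_radius = 0.75,
                       landmark_noise_sd = 0.3125,
                       max_translation = 100,
                       random_pose = TRUE,
                       seed = 1L,
                       catalog = implant_site_catalog()) {
  if (is.null(true_proj_angles)) {
    true_proj_angles <- data.frame(site = catalog$site,
                                   sagittal = catalog$default_sagittal,
                                   dorsal = catalog$default_dorsal)
  }
  if (!all(c("site", "sagittal", "dorsal") %in% names(true_proj_angles))) {
    osic_stop("true_proj_angles needs columns site, sagittal, dorsal",
              "osic_spec_error")
  }
  if (any(abs(c(true_proj_angles$sagittal, true_proj_angles$dorsal)) >= 90)) {
    osic_stop("infeasible angle prescription: |angle| must be < 90 degrees",
              "osic_spec_error")
  }
  if (landmark_noise_sd < 0) osic_stop("landmark_noise_sd must be >= 0", "osic_spec_error")
  if (implant_length <= 0) osic_stop("implant_length must be > 0", "osic_spec_error")
  if (length(safety_offsets) == 1L) safety_offsets <- rep(safety_offsets, 4L)
  if (length(safety_offsets) != 4L || any(safety_offsets <= 0)) {
    osic_stop("safety_offsets must be 1 or 4 positive values (mm)", "osic_spec_error")
  }
  structure(list(n_cases = as.integer(n_cases),
                 true_proj_angles = true_proj_angles,
                 implant_length = implant_length,
                 safety_offsets = safety_offsets,
                 implant_radius = implant_radius,
                 landmark_noise_sd = landmark_noise_sd,
                 max_translation = max_translation,
                 random_pose = isTRUE(random_pose),
                 seed = as.integer(seed),
                 catalog = catalog),
            class = "scene_spec")
}

# Canonical landmark template (mm). Frames evaluate to the identity basis:
# X = (1,0,0), Y = (0,1,0), Z = (0,0,1), with C1 20 mm cranial to C2.
canonical_landmarks <- function() {
  list(C2 = list(O = c(0, 0, 4), A = c(15, 0, 0), B = c(-15, 0, 0)),
       C1 = list(O = c(20, 0, 4), A = c(35, 0, 0), B = c(5, 0, 0)))
}

#' Generate a synthetic scene with known ground truth
#'
#' For every case: the canonical C1/C2 landmark template; for each catalog
#' site an implant whose exit point is constructed from the insertion point
#' plus `implant_length` along the direction realizing the prescribed
#' projected angles; four safety points at the prescribed perpendicular
#' offsets in two orthogonal planes through the axis, placed at mid-corridor
#' (75% of corridor length for sagittal sites directed toward the vertebral
#' canal); and the exact ground-truth angles implied by the construction.
#' Each case is posed by a random rigid transform (uniform rotation via the
#' quaternion method, translation uniform within `max_translation`).
#' Deterministic for a fixed seed.
#'
#' @param spec a [scene_spec()].
#' @return a `synthetic_scene`: list with `spec` and `cases`; each case has
#'   `landmarks` (posed O/A/B per vertebra), `implants` (posed
#'   insertion/exit/safety points per site), `truth` (data frame of true
#'   ProjA, SafA, widths, length per site) and the pose.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  cat <- spec$catalog
  ang <- spec$true_proj_angles
  with_seed(spec$seed, {
    cases <- lapply(seq_len(spec$n_cases), function(ci) {
      pose <- if (spec$random_pose) {
        list(R = random_rotation_matrix(),
             t = stats::runif(3L, -spec$max_translation, spec$max_translation))
      } else {
        list(R = diag(3), t = c(0, 0, 0))
      }
      lm <- canonical_landmarks()
      implants <- list(); truth <- list()
      for (k in seq_len(nrow(cat))) {
        entry <- cat[k, ]
        a <- ang[ang$site == entry$site, ]
        if (nrow(a) != 1L) {
          osic_stop(sprintf("no angle prescription for site %s", entry$site),
                    "osic_spec_error")
        }
        fr <- lm[[entry$frame]]
        # canonical frames are the identity basis, so anatomical components
        # can be laid down directly in template coordinates
        lat <- switch(entry$laterality, right = 3, left = -3, midline = 0)
        I <- fr$O + c(2, lat, -4)
        dir <- direction_from_angles(a$sagittal, a$dorsal)
        E <- I + spec$implant_length * dir
        frac <- if (isTRUE(entry$canal_directed)) 0.75 else 0.5
        P <- I + frac * spec$implant_length * dir
        u0 <- cross3(dir, c(0, 0, 1))
        if (norm3(u0) < 1e-6) u0 <- cross3(dir, c(0, 1, 0))
        u <- unit3(u0)
        w <- unit3(cross3(dir, u))
        h <- spec$safety_offsets
        S <- list(P + h[1L] * u, P - h[2L] * u, P + h[3L] * w, P - h[4L] * w)
        m <- frac * spec$implant_length
        r <- spec$implant_radius
        true_saf <- vapply(h, function(hi) {
          (atan2(hi, m) - asin(r / sqrt(m^2 + hi^2))) * DEG
        }, 0)
        implants[[entry$site]] <- list(
          insertion = rigid_transform(I, pose$R, pose$t),
          exit = rigid_transform(E, pose$R, pose$t),
          S = lapply(S, rigid_transform, rotation = pose$R, translation = pose$t),
          r = r)
        truth[[entry$site]] <- data.frame(
          site = entry$site, frame = entry$frame,
          sagittal = a$sagittal, dorsal = if (entry$sagittal_site) NA_real_ else a$dorsal,
          saf_a1 = true_saf[1L], saf_a2 = true_saf[2L],
          saf_a3 = true_saf[3L], saf_a4 = true_saf[4L],
          width_plane1 = h[1L] + h[2L], width_plane2 = h[3L] + h[4L],
          implant_length = spec$implant_length, stringsAsFactors = FALSE)
      }
      posed_lm <- lapply(lm, function(v) lapply(v, rigid_transform,
                                                rotation = pose$R, translation = pose$t))
      list(case = sprintf("case%03d", ci), landmarks = posed_lm,
           implants = implants, truth = do.call(rbind, truth), pose = pose)
    })
    structure(list(spec = spec, cases = cases), class = "synthetic_scene")
  })
}

#' Export a synthetic scene as an ROI dataset
#'
#' Serializes the scene's landmark and implant points into the labelled ROI
#' point format consumed by [compute_implant_angles()], closing the loop
#' between the generator and the main pipeline.
#'
#' @param scene a [generate_scene()] result.
#' @param landmark_sets optional replacement landmark replicates (from
#'   [perturb_landmarks()]); when given, one dataset per replicate is
#'   returned.
#' @return an [roi_dataset()] (or a list of them, one per replicate).
#' @export
scene_to_roi <- function(scene, landmark_sets = NULL) {
  stopifnot(inherits(scene, "synthetic_scene"))
  cat <- scene$spec$catalog
  one <- function(lmset) {
    rows <- list()
    for (cs in scene$cases) {
      lm <- if (is.null(lmset)) cs$landmarks else lmset[[cs$case]]
      for (vert in c("C1", "C2")) {
        for (role in c("O", "A", "B")) {
          rows[[length(rows) + 1L]] <- data.frame(
            case = cs$case, vertebra = vert, site = paste0("frame_", vert),
            role = paste0("landmark_", role),
            x = lm[[vert]][[role]][1L], y = lm[[vert]][[role]][2L],
            z = lm[[vert]][[role]][3L])
        }
      }
      for (site in names(cs$implants)) {
        imp <- cs$implants[[site]]
        vert <- catalog_entry(cat, site)$vertebra
        pts <- c(list(insertion = imp$insertion, exit = imp$exit),
                 stats::setNames(imp$S, paste0("safety_", 1:4)))
        for (role in names(pts)) {
          rows[[length(rows) + 1L]] <- data.frame(
            case = cs$case, vertebra = vert, site = site, role = role,
            x = pts[[role]][1L], y = pts[[role]][2L], z = pts[[role]][3L])
        }
      }
    }
    roi_dataset(do.call(rbind, rows))
  }
  if (is.null(landmark_sets)) one(NULL) else lapply(landmark_sets, one)
}

#' Perturb anatomical landmarks with placement noise
#'
#' Adds isotropic Gaussian displacement (SD `sd` mm per coordinate) to every
#' O/A/B landmark of every case, independently per replicate; implant and
#' safety points are untouched. Emulates repeated landmark placement by
#' different operators. Deterministic for a fixed seed.
#'
#' @param scene a [generate_scene()] result.
#' @param sd noise SD in mm (>= 0); default from the scene spec.
#' @param n_replicates number of replicate landmark sets (default 4 = 2
#'   observers x 2 repeats).
#' @param seed integer seed.
#' @return list of `n_replicates` landmark sets; each is a per-case list of
#'   perturbed `C1`/`C2` O/A/B landmarks.
#' @export
perturb_landmarks <- function(scene, sd = NULL, n_replicates = 4L, seed = 1L) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (is.null(sd)) sd <- scene$spec$landmark_noise_sd
  if (sd < 0 || n_replicates < 1L) {
    osic_stop("sd must be >= 0 and n_replicates >= 1", "osic_spec_error")
  }
  with_seed(seed, {
    lapply(seq_len(n_replicates), function(rep_i) {
      sets <- lapply(scene$cases, function(cs) {
        lapply(cs$landmarks, function(vert) {
          lapply(vert, function(p) p + stats::rnorm(3L, sd = sd))
        })
      })
      stats::setNames(sets, vapply(scene$cases, `[[`, "", "case"))
    })
  })
}

#' Landmark-placement error experiment
#'
#' Emulates the replicate-landmark study design: for each case, 4 replicate
#' sets of the 6 anatomical-axis landmarks (2 observers x 2 repeats) are drawn
#' with placement noise; every site's projected angles are recomputed under
#' each replicate's frames (implant points held fixed); and the resulting
#' quadruples are analysed with [landmark_proja_analysis()] (per-item gold
#' standard = mean of the 4 values).
#'
#' @param spec a [scene_spec()]; `spec$landmark_noise_sd` sets the noise
#'   scale and `spec$seed` the randomness.
#' @param n_replicate_sets number of replicate landmark sets (default 4).
#' @param variant tolerance-limit variant, see [tolerance_limits()].
#' @return list with `report` (the [landmark_proja_analysis()] output),
#'   `values` (the raw replicate ProjA values) and `scene`.
#' @export
landmark_error_experiment <- function(spec, n_replicate_sets = 4L,
                                      variant = "kfactor") {
  stopifnot(inherits(spec, "scene_spec"))
  scene <- generate_scene(spec)
  reps <- perturb_landmarks(scene, sd = spec$landmark_noise_sd,
                            n_replicates = n_replicate_sets,
                            seed = spec$seed + 1L)
  cat <- spec$catalog
  obs_of <- function(i) ((i - 1L) %/% 2L) + 1L
  rep_of <- function(i) ((i - 1L) %% 2L) + 1L
  n_angles <- sum(lengths(cat$reported))
  n_rows <- n_replicate_sets * length(scene$cases) * n_angles
  col_item <- character(n_rows); col_case <- character(n_rows)
  col_site <- character(n_rows); col_plane <- character(n_rows)
  col_frame <- character(n_rows); col_obs <- integer(n_rows)
  col_rep <- integer(n_rows); col_val <- numeric(n_rows)
  k <- 0L
  for (ri in seq_len(n_replicate_sets)) {
    for (cs in scene$cases) {
      lm <- reps[[ri]][[cs$case]]
      frames <- list(C1 = build_frame(lm$C1$O, lm$C1$A, lm$C1$B, "C1"),
                     C2 = build_frame(lm$C2$O, lm$C2$A, lm$C2$B, "C2"))
      for (si in seq_len(nrow(cat))) {
        entry <- cat[si, ]
        imp <- cs$implants[[entry$site]]
        v <- to_anatomical(frames[[entry$frame]], imp$insertion, imp$exit)
        pa <- projected_angles(v, reported = entry$reported[[1L]])
        for (plane in entry$reported[[1L]]) {
          k <- k + 1L
          col_item[k] <- paste(cs$case, entry$site, plane, sep = "|")
          col_case[k] <- cs$case; col_site[k] <- entry$site
          col_plane[k] <- plane; col_frame[k] <- entry$frame
          col_obs[k] <- obs_of(ri); col_rep[k] <- rep_of(ri)
          col_val[k] <- pa[[plane]]
        }
      }
    }
  }
  values <- data.frame(item = col_item, case = col_case, site = col_site,
                       plane = col_plane, frame = col_frame,
                       observer = col_obs, rep = col_rep, value = col_val,
                       stringsAsFactors = FALSE)
  list(report = landmark_proja_analysis(values, variant = variant),
       values = values, scene = scene)
}
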