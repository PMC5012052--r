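test_that("validation table fixture loads completely", {
  tbl <- load_validation_table()
  expect_identical(nrow(tbl), 60L)
  expect_identical(length(unique(tbl$case)), 12L)
  expect_equal(sum(tbl$gold_standard), 12)
  # spot values
  expect_equal(tbl$proj_a1[tbl$case == "78" & tbl$source == "gold_standard"], 34.51)
  expect_equal(tbl$proj_a1[tbl$case == "22" & tbl$source == "observer1_rep1"], 25.67)
  # missing a source row is a completeness error
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(as.data.frame(tbl)[-1, 1:9], f, row.names = FALSE)
  expect_error(load_validation_table(f), class = "osic_completeness_error")
})

test_that("the site catalog has the published multiplicities", {
  cat13 <- implant_site_catalog()
  expect_identical(nrow(cat13), 13L)
  expect_identical(sum(cat13$sagittal_site), 3L)
  expect_identical(sum(!cat13$sagittal_site), 10L)
  expect_setequal(cat13$id[!cat13$sagittal_site], 0:9)
  expect_true(all(cat13$frame[cat13$corridor == "C1-C2 transarticular"] == "C1"))
  expect_true(all(lengths(cat13$reported[cat13$sagittal_site]) == 1L))
  expect_true(all(lengths(cat13$reported[!cat13$sagittal_site]) == 2L))
})

test_that("scene generation is deterministic and recovers prescribed truth", {
  spec <- scene_spec(n_cases = 3, seed = 7)
  s1 <- generate_scene(spec)
  s2 <- generate_scene(spec)
  expect_identical(s1, s2)
  s3 <- generate_scene(scene_spec(n_cases = 3, seed = 8))
  expect_false(identical(s1$cases[[1]]$implants[[1]]$insertion,
                         s3$cases[[1]]$implants[[1]]$insertion))

  # forward recomputation through the full pipeline reproduces ground truth,
  # random rigid pose notwithstanding
  roi <- scene_to_roi(s1)
  res <- compute_implant_angles(roi, radius = spec$implant_radius, signed = TRUE)
  for (cs in s1$cases) {
    sub <- res[res$case == cs$case, ]
    m <- merge(sub, cs$truth, by = "site")
    expect_equal(m$proj_a1, m$sagittal, tolerance = 1e-9)
    ok <- !is.na(m$dorsal)
    expect_equal(m$proj_a2[ok], m$dorsal[ok], tolerance = 1e-9)
    for (k in paste0("saf_a", 1:4)) {
      expect_equal(m[[paste0(k, ".x")]], m[[paste0(k, ".y")]], tolerance = 1e-9)
    }
    expect_equal(m$width_plane1.x, m$width_plane1.y, tolerance = 1e-9)
    expect_equal(m$implant_length.x, m$implant_length.y, tolerance = 1e-9)
  }

  expect_error(scene_spec(true_proj_angles = data.frame(site = "s", sagittal = 95,
                                                        dorsal = 0)),
               class = "osic_spec_error")
})

test_that("landmark perturbation is seeded, scaled and leaves implants alone", {
  spec <- scene_spec(n_cases = 2, seed = 3)
  scene <- generate_scene(spec)
  r0 <- perturb_landmarks(scene, sd = 0, n_replicates = 2, seed = 1)
  expect_equal(r0[[1]]$case001$C1$O, scene$cases[[1]]$landmarks$C1$O)
  r1 <- perturb_landmarks(scene, sd = 0.3, n_replicates = 2, seed = 1)
  r1b <- perturb_landmarks(scene, sd = 0.3, n_replicates = 2, seed = 1)
  expect_identical(r1, r1b)
  expect_false(identical(r1[[1]], r1[[2]]))

  # empirical displacement SD approximates the nominal sd
  sd_target <- 0.25
  reps <- perturb_landmarks(scene, sd = sd_target, n_replicates = 600, seed = 9)
  disp <- unlist(lapply(reps, function(rep_set) {
    mapply(function(vert, true_vert) {
      mapply(function(p, q) p - q, vert, true_vert)
    }, rep_set$case001, scene$cases[[1]]$landmarks)
  }))
  expect_equal(sd(disp), sd_target, tolerance = 0.05)
})

test_that("landmark error experiment collapses at zero noise and orders errors", {
  spec0 <- scene_spec(n_cases = 4, landmark_noise_sd = 0, seed = 5)
  res0 <- suppressWarnings(landmark_error_experiment(spec0))
  expect_true(all(abs(res0$report$concordance$tl_high -
                        res0$report$concordance$tl_low) < 1e-9))
  expect_true(all(res0$report$absolute_errors$mean_abs < 1e-9))

  spec <- scene_spec(n_cases = 30, landmark_noise_sd = 0.3125, seed = 6)
  res <- landmark_error_experiment(spec)
  ae <- res$report$absolute_errors
  single <- ae$mean_abs[ae$comparison == "single"]
  mean2obs <- ae$mean_abs[ae$comparison == "mean_2_obs"]
  mean2rep <- ae$mean_abs[ae$comparison == "mean_2_rep"]
  expect_gt(single, 0)
  expect_lt(mean2obs, single)
  expect_lt(mean2rep, single)
  cc <- res$report$concordance
  expect_true(all(c("sagittal", "dorsal", "C1", "C2") %in% cc$subgroup))
  # GS-vs-single n = cases x sites' reported angles x 4 replicates
  n_angles <- sum(lengths(implant_site_catalog()$reported))
  expect_equal(cc$n[cc$value2 == "Single value"], 30 * n_angles * 4)
})
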