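test_that("flux plate validation rejects malformed input with informative errors", {
  p <- make_toy_plate()
  ## layout referencing an absent well names the well
  bad_layout <- rbind(p$layout, data.frame(well = "W99", subject = "S1",
                                           group = "control", scheme = "A"))
  expect_error(flux_plate(p$traces, bad_layout), "W99")
  ## a trace missing an entire section names the section
  tr <- p$traces[!(p$traces$well == "WA" & p$traces$section == "inj2"), ]
  expect_error(flux_plate(tr, p$layout), "inj2")
  ## ragged cycle counts rejected
  tr2 <- p$traces[-1, ]
  expect_error(flux_plate(tr2, p$layout), "ragged|cycle")
  ## unknown scheme rejected
  tr3 <- p$traces; tr3$scheme[1] <- "D"
  expect_error(flux_plate(tr3, p$layout), "scheme")
  ## negative OCR rejected unless tolerated
  tr4 <- p$traces; tr4$ocr[1] <- -5
  expect_error(flux_plate(tr4, p$layout), "negative OCR")
  expect_s3_class(flux_plate(tr4, p$layout, allow_negative_ocr = TRUE), "flux_plate")
})

test_that("plate CSV round-trip preserves the plate", {
  dir <- withr::local_tempdir()
  sim <- simulate_flux_plate(cohort_spec(seed = 1, wells_per_subject_per_scheme = 2))
  tp <- file.path(dir, "tr.csv"); lp <- file.path(dir, "ly.csv")
  write_flux_plate(sim$plate, tp, lp)
  back <- read_flux_plate(tp, lp)
  expect_equal(back$layout, sim$plate$layout)
  a <- sim$plate$traces[order(sim$plate$traces$well, sim$plate$traces$section,
                              sim$plate$traces$cycle), ]
  b <- back$traces[order(back$traces$well, back$traces$section, back$traces$cycle), ]
  expect_equal(b$ocr, a$ocr, tolerance = 1e-12)
  expect_error(read_flux_plate(file.path(dir, "nope.csv"), lp), "not found")
})

test_that("section summaries follow the configured policy", {
  p <- make_toy_plate()
  ## constant cycles: basal mean equals the constant
  s <- summarise_sections(p)
  expect_equal(s$ocr_basal[s$scheme == "A"], 100)
  ## non-constant FCCP section takes the max under the default policy
  tr <- p$traces
  tr$ocr[tr$well == "WB" & tr$section == "inj1"] <- c(150, 180, 170)
  s2 <- summarise_sections(flux_plate(tr, p$layout))
  expect_equal(s2$ocr_inj1[s2$scheme == "B"], 180)
  ## mean-everywhere on constant traces is identical to the default
  s3 <- summarise_sections(p, summary_policy("mean", "mean", "mean", "mean", "mean"))
  expect_equal(s3[order(s3$well), ], s[order(s$well), ], ignore_attr = TRUE)
  expect_error(summary_policy(basal = "median"), "mean")
})

test_that("well parameters match the stated stress-test algebra", {
  p <- make_toy_plate(ocr_a = c(100, 40, 20), ocr_b = c(100, 180, 20))
  wp <- compute_well_parameters(summarise_sections(p))
  val <- function(param) wp$value[wp$parameter == param]
  expect_equal(val("basal_respiration"), c(80, 80))  # schemes A and B
  expect_equal(val("atp_linked_respiration"), 60)
  expect_equal(val("proton_leak"), 20)
  expect_equal(val("coupling_efficiency"), 75)
  expect_equal(val("maximal_respiration"), 160)
  expect_equal(val("spare_respiratory_capacity"), 2)
  expect_equal(val("glycolysis"), 12)
  expect_equal(val("glycolytic_capacity"), 27)
  expect_equal(val("nonglycolytic_acidification"), 8)
  ## decomposition holds exactly: basal = ATP-linked + proton leak
  expect_identical(val("basal_respiration")[1],
                   val("atp_linked_respiration") + val("proton_leak"))
})

test_that("boundary and degenerate wells are flagged, not silently numeric", {
  ## post-oligomycin equal to basal: zero ATP-linked, 0% coupling
  p <- make_toy_plate(ocr_a = c(100, 100, 20))
  wp <- compute_well_parameters(summarise_sections(p))
  expect_equal(wp$value[wp$parameter == "atp_linked_respiration"], 0)
  expect_equal(wp$value[wp$parameter == "coupling_efficiency"], 0)
  ## non-positive denominator -> NA, never a number
  p2 <- make_toy_plate(ocr_a = c(20, 10, 20))
  wp2 <- compute_well_parameters(summarise_sections(p2))
  expect_true(is.na(wp2$value[wp2$parameter == "coupling_efficiency"]))
})

test_that("parameters agree with brute-force recomputation from raw cycles", {
  set.seed(31)
  for (rep in 1:5) {
    ocr_a <- sort(runif(3, 10, 200), decreasing = TRUE)
    ocr_b <- c(runif(1, 50, 100), runif(1, 150, 250), runif(1, 5, 30))
    ecar_c <- c(runif(1, 15, 25), runif(1, 30, 40), runif(1, 2, 10))
    p <- make_toy_plate(ocr_a = ocr_a, ocr_b = ocr_b, ecar_c = ecar_c)
    ## jitter cycles so min/mean/max rules actually differ
    p$traces$ocr <- p$traces$ocr * (1 + 0.05 * sin(seq_len(nrow(p$traces))))
    p$traces$ecar <- p$traces$ecar * (1 + 0.05 * cos(seq_len(nrow(p$traces))))
    wp <- compute_well_parameters(summarise_sections(p))
    for (w in unique(p$traces$well)) {
      expected <- oracle_well_params(p$traces, w)
      for (param in names(expected)) {
        got <- wp$value[wp$well == w & wp$parameter == param]
        expect_equal(got, expected[[param]], tolerance = 1e-12)
      }
    }
  }
})

test_that("scaling every OCR by c scales rate parameters and fixes ratios", {
  p <- make_toy_plate()
  p2 <- p
  p2$traces$ocr <- p2$traces$ocr * 3.7
  w1 <- compute_well_parameters(summarise_sections(p))
  w2 <- compute_well_parameters(summarise_sections(p2))
  v <- function(wp, param) wp$value[wp$parameter == param]
  for (ratio in c("coupling_efficiency", "spare_respiratory_capacity")) {
    expect_equal(v(w2, ratio), v(w1, ratio), tolerance = 1e-12)
  }
  for (rate in c("basal_respiration", "atp_linked_respiration", "proton_leak",
                 "maximal_respiration", "nonmito_respiration")) {
    expect_equal(v(w2, rate), 3.7 * v(w1, rate), tolerance = 1e-12)
  }
})

test_that("subject aggregation pools wells into mean and sample SD", {
  ## three scheme-A wells with basal mitochondrial respiration 70, 80, 90
  tr <- rbind(
    transform(expand.grid(section = c("basal", "inj1", "inj2"), cycle = 1:3),
              well = "W1", scheme = "A",
              ocr = c(90, 40, 20)[match(section, c("basal", "inj1", "inj2"))],
              ecar = 20),
    transform(expand.grid(section = c("basal", "inj1", "inj2"), cycle = 1:3),
              well = "W2", scheme = "A",
              ocr = c(100, 40, 20)[match(section, c("basal", "inj1", "inj2"))],
              ecar = 20),
    transform(expand.grid(section = c("basal", "inj1", "inj2"), cycle = 1:3),
              well = "W3", scheme = "A",
              ocr = c(110, 40, 20)[match(section, c("basal", "inj1", "inj2"))],
              ecar = 20))
  layout <- data.frame(well = c("W1", "W2", "W3"), subject = "S1",
                       group = "patient", scheme = "A")
  wp <- compute_well_parameters(summarise_sections(flux_plate(tr, layout)))
  prof <- suppressWarnings(aggregate_subjects(wp, layout))
  basal <- prof[prof$parameter == "basal_respiration", ]
  expect_equal(basal$mean, 80)
  expect_equal(basal$sd, 10)
  expect_equal(basal$n, 3L)
})

test_that("single-well subjects report an undefined SD; cross-scheme ratios use subject means", {
  p <- make_toy_plate(ocr_a = c(100, 40, 20), ocr_b = c(100, 180, 20))
  prof <- bioenergetic_profile(p)
  ce <- prof[prof$parameter == "coupling_efficiency", ]
  expect_equal(ce$mean, 75)
  expect_true(is.na(ce$sd))  # one well -> sample SD undefined
  ## ATP-linked 60 (scheme A), maximal 160 (scheme B) -> ratio 0.375
  alm <- prof[prof$parameter == "atp_linked_to_maximal", ]
  expect_equal(alm$mean, 0.375)
  expect_true(is.na(alm$sd))
  ## a subject missing scheme B entirely is flagged, run continues
  pa <- p
  keepw <- pa$layout$well[pa$layout$scheme != "B"]
  plate_a <- flux_plate(pa$traces[pa$traces$well %in% keepw, ],
                        pa$layout[pa$layout$well %in% keepw, ])
  warns <- capture_warnings(prof2 <- bioenergetic_profile(plate_a))
  expect_true(any(grepl("maximal_respiration", warns)))
  expect_true(is.na(prof2$mean[prof2$parameter == "maximal_respiration"]))
})

test_that("group comparison: identical groups give FC 1 and p 1; Bonferroni behaves", {
  p1 <- make_toy_plate(subject = "P1", group = "patient", well_prefix = "P1")
  p2 <- make_toy_plate(subject = "P2", group = "patient", well_prefix = "P2")
  c1 <- make_toy_plate(subject = "C1", group = "control", well_prefix = "C1")
  c2 <- make_toy_plate(subject = "C2", group = "control", well_prefix = "C2")
  plate <- bind_plates(bind_plates(p1, p2), bind_plates(c1, c2))
  comp <- compare_groups(bioenergetic_profile(plate))
  expect_true(all(comp$fc == 1))
  expect_true(all(comp$p_raw == 1))
  ## Bonferroni: adjusted >= raw, equals min(1, 14 x raw)
  sim <- simulate_flux_plate(cohort_spec(seed = 4, wells_per_subject_per_scheme = 2))
  comp2 <- compare_groups(bioenergetic_profile(sim$plate))
  expect_true(all(comp2$p_bonferroni >= comp2$p_raw))
  expect_equal(comp2$p_bonferroni, pmin(1, comp2$p_raw * 14))
  expect_true(all(comp2$p_bonferroni[comp2$p_raw >= 1 / 14] == 1))
})

test_that("calibrator wells are excluded from group statistics", {
  p1 <- make_toy_plate(subject = "P1", group = "patient", well_prefix = "P1")
  p2 <- make_toy_plate(subject = "P2", group = "patient", well_prefix = "P2")
  c1 <- make_toy_plate(subject = "C1", group = "control", well_prefix = "C1")
  c2 <- make_toy_plate(subject = "C2", group = "control", well_prefix = "C2")
  cal <- make_toy_plate(ocr_a = c(500, 100, 50), subject = "CAL",
                        group = "calibrator", well_prefix = "X")
  plate <- bind_plates(bind_plates(p1, p2), bind_plates(bind_plates(c1, c2), cal))
  prof <- bioenergetic_profile(plate)
  expect_true("CAL" %in% prof$subject)  # summarised
  comp <- compare_groups(prof)          # but excluded from statistics
  expect_true(all(comp$fc == 1))
})
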