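test_that("cohort_spec validates its fields with named errors", {
  expect_s3_class(cohort_spec(seed = 1), "cohort_spec")
  expect_error(cohort_spec(n_patients = 0), "n_patients")
  expect_error(cohort_spec(wells_per_subject_per_scheme = 0),
               "wells_per_subject_per_scheme")
  expect_error(cohort_spec(coupling_effect = 0), "coupling_effect")
  expect_error(cohort_spec(missing_rate = 1), "missing_rate")
  expect_error(cohort_spec(dap_fc_up = 0.9), "dap_fc_up")
  expect_error(cohort_spec(dap_fc_down = 1.2), "dap_fc_down")
  expect_error(cohort_spec(n_proteins = 10, n_dap_up = 8, n_dap_down = 5),
               "exceed")
  expect_error(cohort_spec(questionnaire_corr = 1), "questionnaire_corr")
})

test_that("zero noise and no effect make patient and control section means identical", {
  spec <- cohort_spec(n_patients = 1, n_controls = 1, noise_cv = 0,
                      subject_cv = 0, coupling_sd = 0, coupling_effect = 1,
                      wells_per_subject_per_scheme = 1, seed = 7)
  sim <- simulate_flux_plate(spec)
  tr <- merge(sim$plate$traces, sim$plate$layout[, c("well", "group")], by = "well")
  agg <- aggregate(cbind(ocr, ecar) ~ group + scheme + section, tr, mean)
  wide <- reshape(agg, direction = "wide", idvar = c("scheme", "section"),
                  timevar = "group")
  expect_equal(wide$ocr.patient, wide$ocr.control)
  expect_equal(wide$ecar.patient, wide$ecar.control)
})

test_that("all four generators are byte-identical under a fixed seed", {
  spec <- cohort_spec(seed = 42, n_proteins = 50, n_metabolites = 30,
                      wells_per_subject_per_scheme = 2)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$flux$plate$traces, b$flux$plate$traces)
  expect_identical(a$proteins$table, b$proteins$table)
  expect_identical(a$metabolites$panel, b$metabolites$panel)
  expect_identical(a$questionnaires$table, b$questionnaires$table)
  ## and a different seed changes the draws
  c <- simulate_flux_plate(cohort_spec(seed = 43, wells_per_subject_per_scheme = 2))
  expect_false(identical(a$flux$plate$traces$ocr, c$plate$traces$ocr))
})

test_that("noise-free plates reproduce the stored ground truth exactly", {
  spec <- cohort_spec(seed = 5, noise_cv = 0, wells_per_subject_per_scheme = 2)
  sim <- simulate_flux_plate(spec)
  tr <- merge(sim$plate$traces, sim$plate$layout[, c("well", "subject")], by = "well")
  for (i in seq_len(nrow(sim$truth))) {
    s <- sim$truth[i, ]
    sub <- tr[tr$subject == s$subject, ]
    expect_equal(unique(sub$ocr[sub$scheme == "A" & sub$section == "basal"]),
                 s$ocr_basal, tolerance = 1e-12)
    expect_equal(unique(sub$ocr[sub$scheme == "A" & sub$section == "inj1"]),
                 s$ocr_oligo, tolerance = 1e-12)
    expect_equal(unique(sub$ocr[sub$scheme == "A" & sub$section == "inj2"]),
                 s$ocr_nonmito, tolerance = 1e-12)
    expect_equal(unique(sub$ocr[sub$scheme == "B" & sub$section == "inj1"]),
                 s$ocr_fccp, tolerance = 1e-12)
    expect_equal(unique(sub$ecar[sub$scheme == "C" & sub$section == "inj2"]),
                 s$ecar_nonglyco, tolerance = 1e-12)
  }
  ## true post-oligomycin OCR lies between the non-mitochondrial and basal OCR
  expect_true(all(sim$truth$ocr_oligo > sim$truth$ocr_nonmito))
  expect_true(all(sim$truth$ocr_oligo < sim$truth$ocr_basal))
})

test_that("moving coupling_effect toward 1 moves the expected group FC toward 1", {
  fc_at <- function(eff) {
    fcs <- vapply(1:5, function(s) {
      sim <- simulate_flux_plate(cohort_spec(seed = s, coupling_effect = eff,
                                             noise_cv = 0.03,
                                             wells_per_subject_per_scheme = 3))
      comp <- compare_groups(bioenergetic_profile(sim$plate))
      comp$fc[comp$parameter == "coupling_efficiency"]
    }, numeric(1))
    mean(fcs)
  }
  f70 <- fc_at(0.70); f87 <- fc_at(0.87); f100 <- fc_at(1.0)
  expect_true(abs(f100 - 1) < abs(f87 - 1))
  expect_true(abs(f87 - 1) < abs(f70 - 1))
})

test_that("protein generator spikes the declared fold changes and keeps ground truth consistent", {
  spec <- cohort_spec(seed = 11, n_proteins = 200, n_dap_up = 5, n_dap_down = 3,
                      dap_fc_up = 1.5, dap_fc_down = 0.7)
  sim <- simulate_protein_table(spec)
  expect_true(all(sim$truth$accession[sim$truth$spiked] %in% sim$table$accession))
  expect_equal(sum(sim$truth$true_fc == 1.5), 5)
  expect_equal(sum(sim$truth$true_fc == 0.7), 3)
  ## null spike design -> all true FCs are 1
  null_sim <- simulate_protein_table(cohort_spec(seed = 11, n_proteins = 50,
                                                 n_dap_up = 0, n_dap_down = 0))
  expect_true(all(null_sim$truth$true_fc == 1))
})

test_that("with vanishing noise the protein screen estimates the spiked FC exactly", {
  spec <- cohort_spec(seed = 3, n_proteins = 40, n_dap_up = 2, n_dap_down = 1,
                      protein_cv = 0)
  sim <- simulate_protein_table(spec)
  thr <- list(upper = 1.1, lower = 1 / 1.1)
  scr <- test_proteins(sim$table, sim$groups, thr)
  m <- merge(as.data.frame(scr), sim$truth, by = "accession")
  expect_equal(m$fc, m$true_fc, tolerance = 1e-9)
})

test_that("metabolite missingness follows the left-censoring rate", {
  sim0 <- simulate_metabolite_table(cohort_spec(seed = 8, missing_rate = 0,
                                                n_metabolites = 50))
  expect_false(anyNA(sim0$panel[, sim0$groups$subject]))
  sim <- simulate_metabolite_table(cohort_spec(seed = 8, missing_rate = 0.012,
                                               n_metabolites = 181))
  x <- as.matrix(sim$panel[, sim$groups$subject])
  frac <- mean(is.na(x))
  ## binomial 95% band around 1.2% with 181 x 10 cells
  band <- qbinom(c(0.025, 0.975), length(x), 0.012) / length(x)
  expect_gte(frac, band[1])
  expect_lte(frac, band[2])
  ## censoring is at the low end: every missing compound's LOD is below its mean
  expect_true(all(sim$lod < rowMeans(x, na.rm = TRUE) * 2))
})

test_that("questionnaire tables respect ranges and the FSMC constructional identity", {
  sim <- simulate_questionnaires(cohort_spec(seed = 9))
  tab <- sim$table
  expect_equal(tab$fsmc_total, tab$fsmc_motor + tab$fsmc_cognitive)
  expect_true(all(tab$fsmc_motor >= 10 & tab$fsmc_motor <= 50))
  expect_true(all(tab$compass31_weighted >= 0 & tab$compass31_weighted <= 100))
  sf <- grep("^sf36_", names(tab), value = TRUE)
  expect_true(all(as.matrix(tab[, sf]) >= 0 & as.matrix(tab[, sf]) <= 100))
  ## unattainable target correlation is logged, not raised
  expect_true(any(grepl("unattainable", sim$run_log)))
})

test_that("questionnaire_corr = 0 yields near-zero sample correlation at large n", {
  sim <- simulate_questionnaires(cohort_spec(seed = 10, n_patients = 150,
                                             n_controls = 150,
                                             questionnaire_corr = 0))
  ## instruments decouple from severity; residual correlation comes only from
  ## the group-mean difference, removed by correlating within patients
  pat <- sim$table[sim$table$group == "patient", ]
  r <- cor(pat$fsmc_total, pat$compass31_weighted)
  expect_lt(abs(r), 0.2)
})

test_that("write_cohort round-trips through plain-text files with a ground-truth sidecar", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(seed = 2, n_proteins = 30, n_metabolites = 20,
                      wells_per_subject_per_scheme = 2)
  cohort <- simulate_cohort(spec)
  paths <- write_cohort(cohort, dir)
  expect_true(all(file.exists(paths)))
  plate <- read_flux_plate(file.path(dir, "flux_traces.csv"),
                           file.path(dir, "flux_layout.csv"))
  expect_equal(plate$traces$ocr, cohort$flux$plate$traces$ocr, tolerance = 1e-12)
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$spec$seed, 2)
  expect_equal(sort(truth$spiked_proteins$accession),
               sort(cohort$proteins$truth$accession[cohort$proteins$truth$spiked]))
})
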