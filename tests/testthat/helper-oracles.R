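# Hand-built fixtures and independent brute-force oracles used across tests.

# A minimal plate: one subject per group, one well per scheme, constant cycles
# set directly from the section values given (list: scheme -> c(basal, inj1,
# inj2)), for both signals unless ecar is supplied separately.
make_toy_plate <- function(ocr_a = c(100, 40, 20),
                           ocr_b = c(100, 180, 20),
                           ecar_c = c(20, 35, 8),
                           subject = "S1", group = "control",
                           well_prefix = "W") {
  rows <- list()
  wells <- character(0)
  add_well <- function(well, scheme, ocr, ecar) {
    for (si in 1:3) {
      sec <- c("basal", "inj1", "inj2")[si]
      for (cy in 1:3) {
        rows[[length(rows) + 1L]] <<- data.frame(
          well = well, scheme = scheme, section = sec, cycle = cy,
          ocr = ocr[si], ecar = ecar[si], stringsAsFactors = FALSE)
      }
    }
    wells <<- c(wells, well)
  }
  add_well(paste0(well_prefix, "A"), "A", ocr_a, rep(20, 3))
  add_well(paste0(well_prefix, "B"), "B", ocr_b, rep(20, 3))
  add_well(paste0(well_prefix, "C"), "C", rep(100, 3), ecar_c)
  traces <- do.call(rbind, rows)
  layout <- data.frame(well = wells, subject = subject, group = group,
                       scheme = c("A", "B", "C"), stringsAsFactors = FALSE)
  flux_plate(traces, layout)
}

# Merge two single-subject toy plates into one two-subject plate.
bind_plates <- function(p1, p2) {
  flux_plate(rbind(p1$traces, p2$traces), rbind(p1$layout, p2$layout))
}

# Brute-force recomputation of scheme-level parameters straight from raw
# cycles, independent of summarise_sections/compute_well_parameters.
oracle_well_params <- function(traces, well) {
  tr <- traces[traces$well == well, ]
  scheme <- tr$scheme[1]
  sec <- function(s, sig) tr[tr$section == s, sig]
  if (scheme == "A") {
    basal <- mean(sec("basal", "ocr"))
    oligo <- min(sec("inj1", "ocr"))
    nonmito <- min(sec("inj2", "ocr"))
    list(nonmito_respiration = nonmito,
         basal_respiration = basal - nonmito,
         atp_linked_respiration = basal - oligo,
         proton_leak = oligo - nonmito,
         coupling_efficiency = 100 * (basal - oligo) / (basal - nonmito))
  } else if (scheme == "B") {
    basal <- mean(sec("basal", "ocr"))
    fccp <- max(sec("inj1", "ocr"))
    nonmito <- min(sec("inj2", "ocr"))
    list(nonmito_respiration = nonmito,
         basal_respiration = basal - nonmito,
         maximal_respiration = fccp - nonmito,
         spare_respiratory_capacity = (fccp - nonmito) / (basal - nonmito))
  } else {
    basal <- mean(sec("basal", "ecar"))
    oligo <- min(sec("inj1", "ecar"))
    dg <- min(sec("inj2", "ecar"))
    list(basal_ecar = basal,
         nonglycolytic_acidification = dg,
         glycolysis = basal - dg,
         glycolytic_capacity = oligo - dg,
         glycolytic_reserve = (oligo - dg) / (basal - dg))
  }
}

# Brute-force Benjamini-Hochberg step-up.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Brute-force Pearson r and two-sided p from the definition.
brute_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# Brute-force pooled-variance two-sample t.
brute_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(statistic = t, p.value = 2 * stats::pt(-abs(t), df = n1 + n2 - 2))
}

# Small protein table with explicit abundances; groups P1..P3 / C1..C3.
make_protein_table <- function(abund, peptides = NULL, scans = NULL) {
  n <- nrow(abund)
  tab <- data.frame(accession = sprintf("ACC%02d", seq_len(n)),
                    gene = sprintf("G%02d", seq_len(n)),
                    unique_peptides = peptides %||% rep(5L, n),
                    quant_scans = scans %||% rep(20L, n),
                    mitochondrial = FALSE, stringsAsFactors = FALSE)
  cbind(tab, as.data.frame(abund))
}

protein_groups <- function(n_pat = 3, n_ctl = 3) {
  data.frame(subject = c(sprintf("P%d", seq_len(n_pat)),
                         sprintf("C%d", seq_len(n_ctl))),
             group = rep(c("patient", "control"), c(n_pat, n_ctl)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
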