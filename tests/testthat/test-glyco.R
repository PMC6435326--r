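test_that("log ratios are mutant/control in log10 units", {
  expect_equal(compute_log_ratio(make_record(intensity_medium = 100,
                                             intensity_light = 100)), 0)
  expect_equal(compute_log_ratio(make_record(intensity_medium = 200,
                                             intensity_light = 100)),
               -0.30103, tolerance = 1e-5)
  # a 50-fold lower mutant signal
  expect_equal(compute_log_ratio(make_record(intensity_medium = 5000,
                                             intensity_light = 100)),
               -log10(50))
  expect_equal(-log10(50), -1.69897, tolerance = 1e-5)
  # unpaired: unquantifiable, not zero
  unp <- make_record(intensity_light = NA, paired = FALSE)
  expect_true(is.na(compute_log_ratio(unp)))
})

test_that("fold-change classification uses the 3x and 10x tiers", {
  expect_identical(classify_fold_change(0), "unchanged")
  expect_identical(classify_fold_change(0.3), "unchanged")
  expect_identical(classify_fold_change(-log10(13)), "down10")  # 13-fold down
  expect_identical(classify_fold_change(-log10(5)), "down3")    # 5-fold down
  expect_identical(classify_fold_change(-log10(50)), "down10")
  # boundaries are inclusive towards the stronger category
  expect_identical(classify_fold_change(log10(3)), "up3")
  expect_identical(classify_fold_change(-1), "down10")
  expect_error(classify_fold_change(NA_real_), class = "gt_invalid_argument")
  expect_error(classify_fold_change(Inf), class = "gt_invalid_argument")
})

test_that("channel swap negates ratios and mirrors categories", {
  cfg <- glyco_sim_config(n_proteins = 40, frac_changed = 0.3,
                          effect_log10 = c(-1, -log10(5), log10(4), 1),
                          seed = 12)
  rec <- simulate_glyco_dataset(cfg)$records
  swapped <- rec
  swapped$intensity_medium <- rec$intensity_light
  swapped$intensity_light <- rec$intensity_medium
  r1 <- compute_log_ratio(rec)
  r2 <- compute_log_ratio(swapped)
  expect_equal(r2, -r1)
  ok <- !is.na(r1)
  mirror <- c(unchanged = "unchanged", up3 = "down3", down3 = "up3",
              up10 = "down10", down10 = "up10")
  expect_identical(classify_fold_change(r2[ok]),
                   unname(mirror[classify_fold_change(r1[ok])]))
})

test_that("ten-fold categories are nested within the three-fold bound", {
  r <- seq(-2, 2, by = 0.01)
  cats <- classify_fold_change(r)
  expect_true(all(abs(r[cats %in% c("up10", "down10")]) >= log10(3)))
  expect_true(all(abs(r[cats == "unchanged"]) < log10(3)))
})

test_that("candidate selection is strict at the cutoff and calibrated under the null", {
  m <- structure(list(mu = 0, sigma = 0.55 / 3, cutoff = 0.55,
                      coverage = 0.9973, z = 3, n = 1000L),
                 class = "null_ratio_model")
  expect_false(any(select_candidates(c(0, 0.55, -0.55), m)))
  expect_true(all(select_candidates(c(0.5501, -0.5501), m)))
  sel <- select_candidates(c(0, NA, 1), m)
  expect_identical(attr(sel, "n_unquantifiable"), 1L)
  expect_identical(unname(sel[2]), FALSE)

  # under a pure null the selected fraction approaches 1 - coverage
  fit <- fit_null_model(simulate_flowthrough_ratios(5e4, 0.55 / 3, seed = 30))
  nulls <- simulate_flowthrough_ratios(4e4, 0.55 / 3, seed = 31)
  fp <- mean(select_candidates(nulls, fit))
  p0 <- 1 - fit$coverage
  expect_lt(abs(fp - p0), 3 * sqrt(p0 * (1 - p0) / 4e4))
})

test_that("spiked ten-fold effects are fully recovered at tight null noise", {
  cfg <- glyco_sim_config(n_proteins = 120, frac_changed = 0.1,
                          effect_log10 = c(-1, 1), null_sigma = 0.1,
                          singleton_rate = 0, seed = 13)
  sim <- simulate_glyco_dataset(cfg)
  sites <- aggregate_glycosites(sim$records)
  key <- function(d) paste(d$protein_id, d$site_position)
  truth <- sim$truth[match(key(sites), key(sim$truth)), ]
  site_ratio <- ifelse(is.na(sites$log_ratio_Tn), sites$log_ratio_T,
                       sites$log_ratio_Tn)
  called <- abs(site_ratio) > 0.55
  # sensitivity and sign accuracy both 1 (effects are 10 sigma from null)
  expect_true(all(called[truth$changed]))
  expect_true(all(sign(site_ratio[truth$changed]) ==
                    sign(truth$true_effect[truth$changed])))
  # specificity against ground truth: no unchanged site beyond the cutoff
  expect_false(any(called[!truth$changed]))
})

test_that("site aggregation takes glycoform medians and the class union", {
  rec <- rbind(make_site_records(c(-1, -2, -3)),
               make_site_records(0.1, glycoform = "T"))
  s <- aggregate_glycosites(rec)
  expect_equal(nrow(s), 1L)
  expect_equal(s$log_ratio_Tn, -2)  # median of -1, -2, -3
  expect_identical(s$glycoform_class, "both")
  expect_identical(s$category_Tn, "down10")
  expect_identical(s$category_T, "unchanged")
  expect_equal(s$n_psm, 4L)

  # a glycoform observed only through singletons is unquantified
  rec2 <- make_record(intensity_light = NA, paired = FALSE)
  s2 <- aggregate_glycosites(rec2)
  expect_identical(s2$category_Tn, "unquantified")
  expect_true(is.na(s2$log_ratio_Tn))
  expect_identical(s2$glycoform_class, "Tn-only")

  # conflicting residues at one site key are a data-integrity error
  bad <- rbind(make_record(residue = "S"), make_record(residue = "T"))
  expect_error(aggregate_glycosites(bad), class = "gt_data_integrity")
})

test_that("site aggregation reproduces generator glycoform classes exactly", {
  cfg <- glyco_sim_config(n_proteins = 70, seed = 14)
  sim <- simulate_glyco_dataset(cfg)
  s <- aggregate_glycosites(sim$records)
  key <- function(d) paste(d$protein_id, d$site_position)
  truth <- sim$truth[match(key(s), key(sim$truth)), ]
  expect_identical(s$glycoform_class, truth$glycoform_class)
  expect_identical(s$residue, truth$residue)
})

test_that("protein summaries count sites, classes and direct targets", {
  rec <- rbind(
    make_site_records(-1.2, protein_id = "PA", site_position = 3),
    make_site_records(0.01, protein_id = "PA", site_position = 9,
                      residue = "T"),
    make_site_records(-0.1, protein_id = "PB", site_position = 5),
    make_site_records(-0.2, protein_id = "PB", site_position = 8)
  )
  p <- summarize_proteins(aggregate_glycosites(rec))
  pa <- p[p$protein_id == "PA", ]
  expect_equal(pa$n_glycosites, 2L)
  expect_identical(pa$glycoform_class, "Tn-only")
  expect_identical(pa$category, "down10")
  expect_true(pa$direct_target)    # one site down10, one unchanged
  pb <- p[p$protein_id == "PB", ]
  expect_false(pb$direct_target)
  expect_identical(pb$category, "unchanged")

  # a single-site protein can never be a direct target
  one <- summarize_proteins(aggregate_glycosites(make_site_records(-1.5)))
  expect_false(one$direct_target)
})

test_that("glycoproteome report percentages are coherent", {
  cfg <- glyco_sim_config(n_proteins = 150, frac_changed = 0.2,
                          effect_log10 = c(-1, log10(4)), seed = 15)
  sim <- simulate_glyco_dataset(cfg)
  sites <- aggregate_glycosites(sim$records)
  prots <- summarize_proteins(sites)
  rep <- glycoproteome_report(sites, prots)
  expect_equal(rep$n_sites, nrow(sites))
  expect_equal(rep$n_proteins, length(unique(sites$protein_id)))
  expect_equal(sum(rep$site_class_pct), 100, tolerance = 0.1)
  expect_equal(sum(rep$protein_class_pct), 100, tolerance = 0.1)
  expect_equal(sum(rep$multiplicity_pct), 100, tolerance = 0.1)
  expect_equal(sum(rep$residue_pct), 100, tolerance = 0.1)
  expect_gte(rep$n_proteins_changed_3x, rep$n_proteins_changed_10x)
  expect_output(print(rep), "glycosites")

  # all-Tn input: 100% Tn-only at both levels
  tn <- sim$records[sim$records$glycoform == "Tn", ]
  s_tn <- aggregate_glycosites(tn)
  rep_tn <- glycoproteome_report(s_tn, summarize_proteins(s_tn))
  expect_equal(unname(rep_tn$site_class_pct["Tn-only"]), 100)
  expect_equal(unname(rep_tn$protein_class_pct["Tn-only"]), 100)
})

test_that("peptide-relative positions convert to protein coordinates", {
  expect_equal(site_position_in_protein(7, 101), 107)
  expect_equal(site_position_in_protein(1, 1), 1)
  expect_error(site_position_in_protein(0, 5), class = "gt_invalid_argument")
})

test_that("multiplicity comparison behaves like a two-sided rank test", {
  x <- c(1, 1, 2, 2, 3, 3, 4, 5, 6, 8)
  expect_gte(compare_multiplicity(x, x), 0.99)
  expect_error(compare_multiplicity(numeric(0), x),
               class = "gt_invalid_argument")

  # a +3 shift at n = 50 is detected
  set.seed(77)
  base <- rpois(50, 2) + 1
  expect_lt(compare_multiplicity(base + 3, base), 0.01)

  # agreement with a brute-force permutation null on a 10-vs-10 toy
  y <- c(1, 2, 2, 3, 4, 5, 5, 6, 7, 9)
  p_u <- compare_multiplicity(x, y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  obs <- sum(rk[1:10])
  combos <- utils::combn(20L, 10L)
  w <- colSums(matrix(rk[combos], nrow = 10L))
  p_perm <- mean(abs(w - mean(w)) >= abs(obs - mean(w)) - 1e-9)
  expect_lt(abs(p_u - p_perm), 0.02)
})
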