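test_that("the report simulator is seed-deterministic down to the files", {
  cfg <- faers_sim_config(seed = 7, n_background_reports = 2000,
                          target_drug_reports = 200)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_faers(cfg, dir = d1)
  simulate_faers(cfg, dir = d2)
  for (f in c("demo.txt", "drug.txt", "reac.txt", "manifest.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  # a different seed changes the stream
  simulate_faers(faers_sim_config(seed = 8, n_background_reports = 2000,
                                  target_drug_reports = 200), dir = d2)
  expect_false(identical(readLines(file.path(d1, "demo.txt")),
                         readLines(file.path(d2, "demo.txt"))))
})

test_that("simulated files are accepted unmodified by the quarter reader", {
  dir <- tempfile()
  sim <- simulate_faers(faers_sim_config(seed = 3, n_background_reports = 1500,
                                         target_drug_reports = 150), dir = dir)
  q <- read_faers_quarter(file.path(dir, "demo.txt"), file.path(dir, "drug.txt"),
                          file.path(dir, "reac.txt"))
  expect_equal(nrow(q$demo), nrow(sim$demo))
  expect_equal(q$log$demo_unparseable_dates, 0)
  expect_true(all(q$drug$role_cod %in% c("PS", "C")))
  expect_true(all(nzchar(q$reac$pt)))
})

test_that("duplicates exercise both deduplication tie rules", {
  sim <- simulate_faers(faers_sim_config(seed = 5, n_background_reports = 3000,
                                         target_drug_reports = 300,
                                         duplicate_fraction = 0.1))
  n_dup <- sim$manifest$n_duplicates
  expect_equal(n_dup, floor(0.1 * 3300))
  dup_case <- sim$demo$caseid[duplicated(sim$demo$caseid)]
  expect_equal(length(dup_case), n_dup)
  # per duplicated case the kept record must be the later/higher one
  dd <- deduplicate_cases(sim$demo)
  expect_equal(nrow(dd), length(unique(sim$demo$caseid)))
  sub <- sim$demo[sim$demo$caseid %in% dup_case, ]
  agg_dt <- tapply(sub$fda_dt, sub$caseid, max)
  kept <- dd[dd$caseid %in% dup_case, ]
  expect_true(all(kept$fda_dt == agg_dt[kept$caseid]))
  # both tie rules are present in the stream
  ties <- tapply(sub$fda_dt, sub$caseid, function(x) length(unique(x)) == 1)
  expect_true(any(ties) && any(!ties))
})

test_that("planted effects shift PT probabilities as the manifest records", {
  rr <- 5
  cfg <- faers_sim_config(seed = 11, n_background_reports = 8000,
                          target_drug_reports = 4000,
                          planted_signals = list(list(drug = "TARGETLEUCEL",
                                                      pt = "Acute kidney injury",
                                                      rr = rr)))
  sim <- simulate_faers(cfg)
  man <- sim$manifest
  p_bg <- man$pt_probabilities$baseline[["Acute kidney injury"]]
  p_tg <- man$pt_probabilities$TARGETLEUCEL[["Acute kidney injury"]]
  expect_equal(p_tg, rr * p_bg / (1 + (rr - 1) * p_bg), tolerance = 1e-9)
  # observed PT rate among target reports tracks the manifest probability
  tg_ids <- sim$demo$primaryid[seq_len(8000 + 4000) > 8000]
  reac_tg <- sim$reac[sim$reac$primaryid %in% tg_ids, ]
  obs <- mean(reac_tg$pt == "Acute kidney injury")
  expect_equal(obs, p_tg, tolerance = 0.3)
  # invalid configs name the offending field
  expect_error(faers_sim_config(duplicate_fraction = 1), "duplicate_fraction")
  expect_error(faers_sim_config(planted_signals = list(list(drug = "X",
                                                            pt = "Nope", rr = 2))),
               "planted_signals")
})

test_that("the GWAS simulator is deterministic and self-consistent", {
  cfg <- gwas_sim_config(seed = 13, n_snps = 6, theta = 0.25)
  g1 <- simulate_gwas_pair(cfg)
  g2 <- simulate_gwas_pair(cfg)
  expect_identical(g1$exposure, g2$exposure)
  expect_identical(g1$ld, g2$ld)
  expect_equal(g1$manifest$theta, 0.25)

  # file round-trip through the package readers
  dir <- tempfile()
  simulate_gwas_pair(cfg, dir = dir)
  ex <- read_sumstats(file.path(dir, "exposure.tsv"))
  expect_equal(nrow(ex), nrow(g1$exposure))
  ld <- read_ld_matrix(file.path(dir, "ld.tsv"))
  expect_equal(unname(ld), unname(g1$ld))

  # LD blocks appear in the matrix and attenuate neighbour effects
  gb <- simulate_gwas_pair(gwas_sim_config(seed = 2, n_snps = 3,
                                           ld_block_size = 3, ld_block_r2 = 0.64,
                                           n_null_snps = 0, n_flank_snps = 0,
                                           swap_fraction = 0))
  expect_equal(sum(gb$ld == 0.64), 3 * (9 - 3))
  b <- gb$manifest$true_beta_exp
  expect_equal(length(b), 9)

  expect_error(gwas_sim_config(ld_block_r2 = 2), "ld_block_r2")
  expect_error(gwas_sim_config(swap_fraction = -1), "swap_fraction")
})

test_that("null and planted snapshots calibrate the screen as designed", {
  # one null seed: no ALL-FOUR positive among observed PTs
  cfg0 <- faers_sim_config(seed = 29, n_background_reports = 10000,
                           target_drug_reports = 800)
  sim0 <- simulate_faers(cfg0)
  sp0 <- split_target_background(sim0$demo, sim0$drug, sim0$reac, "TARGETLEUCEL")
  scr0 <- screen_signals(sp0$target, sp0$background, smq_pool = FALSE)
  expect_lte(sum(scr0$positive), 1)

  # one planted seed at rate-ratio 5: the planted pair flags
  cfg1 <- faers_sim_config(seed = 29, n_background_reports = 10000,
                           target_drug_reports = 800,
                           planted_signals = list(list(drug = "TARGETLEUCEL",
                                                       pt = "Urinary incontinence",
                                                       rr = 6)))
  sim1 <- simulate_faers(cfg1)
  sp1 <- split_target_background(sim1$demo, sim1$drug, sim1$reac, "TARGETLEUCEL")
  scr1 <- screen_signals(sp1$target, sp1$background, smq_pool = FALSE)
  expect_true(scr1$positive[scr1$pt == "Urinary incontinence"])
})
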