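test_that("cohort_config validates its invariants", {
  expect_s3_class(cohort_config(), "cohort_config")
  expect_error(cohort_config(aging_rate_mean = -1), "rates")
  expect_error(cohort_config(aging_mix = c(SBS1 = 0.5, SBS5 = 0.2, SBS18 = 0.2)),
               "sum")
  expect_error(cohort_config(vaf_subclonal = c(10, 10)), "95th")
  td <- cohort_config()$treated_design
  td$capox_cycles[1] <- 0
  expect_error(cohort_config(treated_design = td), "zero cycles")
})

test_that("the liver preset zeroes treatment effects but keeps the clock", {
  cfg <- cohort_config("liver")
  expect_identical(cfg$platinum_per_cycle_mean, 0)
  expect_identical(cfg$fiveFU_activation_prob, 0)
  expect_identical(cfg$radio_id8_mean, 0)
  expect_identical(cfg$aging_rate_mean, 43)
})

test_that("simulation is reproducible under a fixed seed", {
  c1 <- simulate_cohort(seed = 5, records = TRUE)
  c2 <- simulate_cohort(seed = 5, records = TRUE)
  expect_identical(c1$context, c2$context)
  expect_identical(c1$records, c2$records)
  expect_identical(c1$sv, c2$sv)
  c3 <- simulate_cohort(seed = 6)
  expect_false(identical(c1$context$SBS96, c3$context$SBS96))
})

test_that("ground truth totals equal the realised context counts", {
  co <- simulate_cohort(seed = 8)
  gt <- co$ground_truth
  expect_identical(unname(rowSums(co$context$SBS96)),
                   as.numeric(gt$aging_sbs + gt$platinum_sbs + gt$fiveFU_sbs))
  expect_identical(unname(rowSums(co$context$DBS78)),
                   as.numeric(gt$aging_dbs + gt$platinum_dbs))
  expect_identical(unname(rowSums(co$context$ID83)),
                   as.numeric(gt$aging_id + gt$radio_id8))
})

test_that("null treatment config gives treated clones the untreated law", {
  cfg <- cohort_config(platinum_per_cycle_mean = 0, fiveFU_activation_prob = 0,
                       radio_id8_mean = 0, sv_del_per_id8 = 0,
                       complex_sv_rate = 0)
  co <- simulate_cohort(cfg, seed = 9)
  gt <- co$ground_truth
  expect_true(all(gt$platinum_sbs == 0))
  expect_true(all(gt$fiveFU_sbs == 0))
  expect_true(all(gt$radio_id8 == 0))
  expect_true(all(gt$radio_sv_del == 0))
})

test_that("subclonal spike-ins mostly vanish under clonal filtering", {
  co <- simulate_cohort(seed = 10, records = TRUE)
  kept <- filter_clonal(co$records)
  sub_before <- sum(co$records$origin == "invitro_subclonal")
  sub_after <- sum(kept$origin == "invitro_subclonal")
  expect_identical(sub_before, nrow(co$meta) * 50L)
  # Beta(4,26) puts ~2% of mass above 0.30; enumeration on the drawn VAFs
  sub <- co$records[co$records$origin == "invitro_subclonal", ]
  expect_identical(sub_after, sum(sub$vaf > 0.30))
  expect_lt(sub_after / sub_before, 0.06)
  # clonal mutations survive essentially completely
  clon <- co$records[co$records$clonal, ]
  expect_gt(sum(clon$vaf > 0.30) / nrow(clon), 0.999)
})

test_that("expanded records reproduce the context matrices through the pipeline", {
  co <- simulate_cohort(seed = 12, records = TRUE)
  clonal <- co$records[co$records$clonal, ]
  for (mt in c("SBS96", "DBS78", "ID83")) {
    m <- build_context_matrix(clonal, co$meta, mt)
    expect_identical(m, co$context[[mt]], info = mt)
  }
})

test_that("write_cohort TSV round-trips losslessly", {
  co <- simulate_cohort(cohort_config(n_donors_untreated = 2,
                                      clones_per_donor = 1),
                        records = TRUE, seed = 13)
  dir <- tempfile(); dir.create(dir)
  write_cohort(co, dir, format = "tsv")
  rec <- read_mutations(file.path(dir, "mutations.tsv"), format = "tsv")
  expect_identical(nrow(rec), nrow(co$records))
  meta <- read_sample_meta(file.path(dir, "meta.tsv"))
  expect_identical(meta$sample_id, co$meta$sample_id)
  m <- build_context_matrix(filter_clonal(rec), meta, "SBS96")
  clonal <- filter_clonal(co$records)
  expect_identical(m, build_context_matrix(clonal, co$meta, "SBS96"))
  if (nrow(co$sv)) {
    sv <- read_sv(file.path(dir, "sv.tsv"))
    expect_identical(nrow(sv), nrow(co$sv))
  }
})

test_that("write_cohort VCF round-trips through read_mutations", {
  co <- simulate_cohort(cohort_config(n_donors_untreated = 1,
                                      clones_per_donor = 1,
                                      age_range = c(20, 30)),
                        records = TRUE, seed = 14)
  dir <- tempfile(); dir.create(dir)
  paths <- write_cohort(co, dir, format = "vcf")
  vcfs <- grep("\\.vcf$", paths, value = TRUE)
  rec <- do.call(rbind, lapply(vcfs, function(p) read_mutations(p, format = "vcf")))
  expect_identical(nrow(rec), nrow(co$records))
  # the channel annotation survives, so context matrices agree exactly
  m <- build_context_matrix(rec[rec$mut_class == "SBS", ], co$meta, "SBS96")
  truth <- co$records[co$records$mut_class == "SBS", ]
  m0 <- build_context_matrix(truth, co$meta, "SBS96")
  expect_identical(m, m0)
  # VAFs survive to write precision
  expect_equal(sort(rec$vaf), sort(co$records$vaf), tolerance = 1e-5)
})

test_that("write_cohort refuses cohorts without records", {
  co <- simulate_cohort(seed = 15)
  expect_error(write_cohort(co, tempfile()), "records")
})
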