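ref <- synthetic_msat_reference()
n_dyads <- length(ref$dyad_pos)

test_that("linker is located exactly in constructed reads", {
  states <- rep("M", n_dyads)
  read <- make_clean_read(ref, states)
  lk <- locate_linker(read, ref)
  expect_equal(lk$status, "ok")
  expect_equal(lk$orientation, "forward")
  expect_equal(nchar(lk$upper_arm), nchar(ref$upper_seq))
  expect_equal(nchar(lk$lower_arm), nchar(ref$upper_seq))
  # same molecule sequenced from the other end
  lk2 <- locate_linker(revcomp_chr(read), ref)
  expect_equal(lk2$status, "ok")
  expect_equal(lk2$orientation, "reverse")
  expect_equal(lk2$upper_arm, lk$upper_arm)
  expect_equal(lk2$lower_arm, lk$lower_arm)
})

test_that("reads without a linker-like substring are rejected", {
  lk <- locate_linker(paste(rep("A", 120), collapse = ""), ref)
  expect_equal(lk$status, "linker_not_found")
})

test_that("linker split recovers true boundaries under sequencing noise", {
  params <- dnmt_params(c_fail = 0.01)
  set.seed(42)
  states <- matrix(sample(c("U", "M"), 300 * n_dyads, TRUE), 300, n_dyads)
  rr <- render_reads(states, ref, params, seq_error_rate = 0.005, seed = 7)
  n_up <- nchar(ref$upper_seq)
  hits <- vapply(rr$reads, function(rd) {
    lk <- locate_linker(rd, ref)
    identical(lk$status, "ok") && nchar(lk$upper_arm) == n_up
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("bisulfite-aware alignment treats C/T as match and scores like the DP oracle", {
  short <- build_reference("TACGGATCCGATTA")
  loc <- short$upper_seq
  all_c <- align_arm(loc, short, "upper")
  expect_equal(unname(all_c$calls), strsplit(loc, "")[[1]])
  expect_equal(all_c$identity, 1.0)

  conv <- chartr("C", "T", loc)
  all_t <- align_arm(conv, short, "upper")
  expect_equal(unname(all_t$calls), strsplit(conv, "")[[1]])
  expect_equal(all_t$identity, 1.0)

  # internal 2-base deletion: score must match the independent DP oracle
  del <- paste0(substr(conv, 1, 5), substr(conv, 8, nchar(conv)))
  res <- align_arm(del, short, "upper")
  expect_equal(res$score, oracle_align_score(loc, del))
  expect_equal(sum(res$calls == "-"), 2L)

  # random mutated arms: C++ score equals the plain-R DP score
  set.seed(11)
  for (i in 1:10) {
    arm <- strsplit(conv, "")[[1]]
    k <- sample(length(arm), 2)
    arm[k] <- sample(c("A", "C", "G", "T"), 2, TRUE)
    if (runif(1) < 0.5) arm <- arm[-sample(length(arm), 1)]
    arm <- paste(arm, collapse = "")
    expect_equal(align_arm(arm, short, "upper")$score,
                 oracle_align_score(loc, arm))
  }
})

test_that("profiles recover dyad states and conversion from clean reads", {
  states <- c("M", "HU", "HL", "U", "M", "U", "HU", "M")[seq_len(n_dyads)]
  read <- make_clean_read(ref, states)
  prof <- extract_read_profile(read, ref)
  expect_true(prof$pass_filter)
  expect_equal(prof$conversion_rate, 1.0)
  expect_equal(prof$identity_upper, 1.0)
  expect_equal(prof$identity_lower, 1.0)
  expect_equal(prof$n_covered_dyads, n_dyads)

  calls <- call_read(prof, ref)
  code <- c(U = "UNMETH", HU = "HEMI_UPPER", HL = "HEMI_LOWER", M = "FULL")
  expect_equal(unname(calls$dyads), unname(code[states]))

  # orientation invariance: the reverse complement gives the same profile
  prof2 <- extract_read_profile(revcomp_chr(read), ref)
  expect_equal(prof2$upper_calls, prof$upper_calls)
  expect_equal(prof2$lower_calls, prof$lower_calls)
  expect_equal(prof2$conversion_rate, prof$conversion_rate)
})

test_that("conversion rate is the T fraction at marked linker Cs", {
  # linker with 6 marked Cs, five converted and one failed
  states <- rep("M", n_dyads)
  read <- make_clean_read(ref, states)
  lk <- locate_linker(read, ref)
  seg <- strsplit(lk$linker_segment, "")[[1]]
  seg[ref$linker_marked[6]] <- "C"
  doctored <- paste0(lk$upper_arm, paste(seg, collapse = ""), lk$lower_arm)
  prof <- extract_read_profile(doctored, ref)
  expect_equal(prof$conversion_rate, 5 / 6)
})

test_that("the conversion estimator is unbiased for the failure rate", {
  params <- dnmt_params(c_fail = 0.011)
  set.seed(5)
  states <- matrix("M", 1500, n_dyads)
  rr <- render_reads(states, ref, params, seed = 13)
  conv <- vapply(rr$reads, function(rd) {
    lk <- locate_linker(rd, ref)
    seg <- strsplit(lk$linker_segment, "")[[1]][ref$linker_marked]
    sum(seg == "T") / sum(seg %in% c("C", "T"))
  }, numeric(1))
  n_trials <- length(conv) * length(ref$linker_marked)
  se <- sqrt(0.011 * 0.989 / n_trials)
  expect_lt(abs(mean(1 - conv) - 0.011), 4 * se)
})

test_that("filtering partitions deterministically with logged reasons", {
  states <- rep("M", n_dyads)
  good <- extract_read_profile(make_clean_read(ref, states), ref)
  bad_conv <- good
  bad_conv$conversion_rate <- 0.80
  bad_id <- good
  bad_id$identity_lower <- 0.5
  flt <- filter_reads(list(good, bad_conv, bad_id),
                      min_conversion = 0.90, min_identity = 0.80)
  expect_length(flt$kept, 1)
  expect_length(flt$rejected, 2)
  reasons <- vapply(flt$rejected, `[[`, "", "reject_reason")
  expect_setequal(reasons, c("low_conversion", "low_identity"))
  expect_false(any(vapply(flt$rejected, `[[`, TRUE, "pass_filter")))

  all_good <- filter_reads(list(good, good))
  expect_length(all_good$rejected, 0)
})

test_that("FASTQ round trip through Biostrings works", {
  params <- dnmt_params()
  states <- matrix("M", 5, n_dyads)
  tmp <- withr::local_tempfile(fileext = ".fastq")
  rr <- render_reads(states, ref, params, seed = 3, fastq = tmp)
  back <- read_hairpin_reads(tmp)
  expect_equal(unname(back), unname(rr$reads))
  expect_equal(names(back), names(rr$reads))
})
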