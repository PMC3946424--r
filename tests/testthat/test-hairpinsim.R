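test_that("synthetic genomes are seed-reproducible with the target GC", {
  g1 <- generate_genome(10000, 0.45, seed = 301)
  g2 <- generate_genome(10000, 0.45, seed = 301)
  expect_identical(g1$sequence, g2$sequence)
  expect_false(identical(g1$sequence, generate_genome(10000, 0.45,
                                                      seed = 302)$sequence))
  gc <- gc_content(g1$sequence)
  sd3 <- 3 * sqrt(0.45 * 0.55 / 10000)
  expect_lt(abs(gc - 0.45), sd3)
  expect_error(generate_genome(10000, 0), "inside")
  expect_error(generate_genome(10000, 1), "inside")
  expect_error(generate_genome(500, 0.4), ">= 1000")
})

test_that("fragments match their genome slices and hit the target mean length", {
  g <- generate_genome(20000, 0.4, seed = 303)
  fr <- draw_fragments(g, 5000, mean_len = 70, shape = 0.35, seed = 304)
  # CLT bound on the sample mean
  sdlog <- 0.35
  sd_len <- 70 * sqrt(exp(sdlog^2) - 1)
  expect_lt(abs(mean(fr$length) - 70), 3 * sd_len / sqrt(5000))
  expect_equal(nrow(draw_fragments(g, 0)), 0L)
  # sequence equals the (oriented) genome slice
  idx <- sample(nrow(fr), 100)
  for (k in idx) {
    slice <- substr(g$sequence, fr$start[k] + 1L, fr$end[k])
    if (fr$strand[k] == "-") slice <- reverse_complement(slice)
    expect_identical(fr$sequence[k], slice)
  }
  expect_identical(fr$end - fr$start, fr$length)
})

test_that("deamination flips terminal C/G with the configured rate profile", {
  g <- generate_genome(5000, 0.5, seed = 305)
  fr <- draw_fragments(g, 2000, seed = 306)
  expect_identical(apply_deamination(fr, 0, seed = 1)$sequence, fr$sequence)
  sat <- apply_deamination(fr, rate_5prime = 1, decay_per_base = 1, seed = 2)
  expect_false(any(grepl("[CG]", sat$sequence)))
  # terminal flip frequency approximates the configured rate
  dam <- apply_deamination(fr, rate_5prime = 0.3, decay_per_base = 0.5,
                           seed = 3)
  firstC <- substr(fr$sequence, 1, 1) == "C"
  flipped <- substr(dam$sequence, 1, 1) == "T"
  phat <- mean(flipped[firstC])
  n <- sum(firstC)
  expect_lt(abs(phat - 0.3), 3 * sqrt(0.3 * 0.7 / n))
})

test_that("denaturation probability is logistic around the melting point", {
  pro <- library_protocol("forked_AT")
  off <- pro$denature_midpoint_offset
  expect_equal(denature_probability(70, 70 + off, pro), 0.5)
  expect_equal(denature_probability(70, -1e6, pro), 0)
  expect_equal(denature_probability(70, 1e6, pro), 1)
  # at fixed length, lower GC means lower Tm means easier denaturation
  lo_gc <- strrep("AT", 20); hi_gc <- paste0(strrep("AT", 15), strrep("GC", 5))
  p <- denature_probability(melting_temperature(c(lo_gc, hi_gc)), 70, pro)
  expect_gt(p[1], p[2])
  # fixed override
  pf <- library_protocol("forked_AT", denature_prob = 0.25)
  expect_equal(denature_probability(c(40, 90), 70, pf), c(0.25, 0.25))
})

test_that("hairpin stem search agrees with exhaustive enumeration", {
  expect_equal(find_hairpin("TTACGAAAAATCGT", min_stem = 4),
               c(i = 2L, j = 10L, m = 4L))
  expect_null(find_hairpin("AAAAAAAAAA"))
  expect_null(find_hairpin(""))
  set.seed(307)
  seqs <- random_dna(150, sample(30:50, 150, TRUE))
  for (s in seqs) {
    hit <- find_hairpin(s, min_stem = 3, max_fill = 10)
    expect_identical(hit, brute_hairpin(s, min_stem = 3, max_fill = 10))
    if (!is.null(hit)) {
      stem5 <- substr(s, hit["i"] + 1L, hit["i"] + hit["m"])
      stem3 <- substr(s, hit["j"] + 1L, hit["j"] + hit["m"])
      expect_identical(stem3, reverse_complement(stem5))
      expect_gte(hit["j"] - (hit["i"] + hit["m"]), 3L)  # loop >= 3
    }
  }
})

test_that("artifact formation chews back the tail and fills in from the 5' end", {
  out <- form_artifact("TTACGAAAAATCGT", 2, 10, 4)
  expect_equal(out, "TTACGAAAAATCGTAA")
  expect_equal(terminal_palindrome_length(out), 6L)

  # i = 0: chew-back only, no artificial fill
  s0 <- paste0("ACGA", "TTTTTT", "TCGT", "GG")   # stem at i=0, j=10, tail GG
  expect_equal(find_hairpin(s0, min_stem = 4, max_fill = 5),
               c(i = 0L, j = 10L, m = 4L))
  t0 <- form_artifact(s0, 0, 10, 4)
  expect_equal(t0, substr(s0, 1, 14))            # 3' tail gone, nothing added
  expect_gte(terminal_palindrome_length(t0), 4L)

  expect_error(form_artifact("TTACGAAAAATCGT", 2, 9, 4), "complementary")
  expect_error(form_artifact("ACGT", 0, 1, 2), "invalid")

  # guarantee: palindrome length of the product is at least i + m
  set.seed(308)
  for (s in random_dna(200, 60)) {
    hit <- find_hairpin(s)
    if (is.null(hit)) next
    art <- form_artifact(s, hit["i"], hit["j"], hit["m"])
    expect_gte(terminal_palindrome_length(art),
               as.integer(hit["i"] + hit["m"]))
  }
})

test_that("library construction respects denaturation and adapter-scheme rules", {
  g <- generate_genome(10000, 0.45, seed = 309)
  fr <- draw_fragments(g, 1500, seed = 310)

  none <- build_library(fr, library_protocol("forked_AT", denature_prob = 0),
                        seed = 311)
  expect_equal(sum(none$truths$is_artifact), 0L)
  expect_equal(nrow(none$molecules), nrow(none$truths))

  for (scheme in c("blunt", "stem_loop_blunt")) {
    lib <- build_library(fr, library_protocol(scheme, denature_prob = 0.6),
                         seed = 312)
    expect_equal(sum(lib$truths$is_artifact), 0L)  # hairpins cannot ligate
    # non-denatured dsDNA is retained, denatured ssDNA is lost
    expect_lt(nrow(lib$molecules[!grepl("dup", lib$molecules$molecule_id), ]),
              nrow(fr))
  }
})

test_that("forced full denaturation recovers the findable-stem fraction exactly", {
  g <- generate_genome(10000, 0.5, seed = 313)
  fr <- draw_fragments(g, 800, seed = 314)
  pro <- library_protocol("forked_AT", denature_prob = 1,
                          hairpin_stability_bonus = 1000)  # stems always stable
  lib <- build_library(fr, pro, seed = 315)
  orig <- !grepl("dup", lib$truths$molecule_id)
  expect_true(all(lib$truths$is_artifact))   # only hairpins survive full melt
  findable <- vapply(fr$sequence, function(s)
    !is.null(find_hairpin(s, pro$min_stem, pro$max_fill, pro$min_loop)),
    logical(1))
  expect_equal(sum(orig), sum(findable))
  # molecules equal form_artifact applied to their fragment
  k <- which(orig)[1:20]
  frag_idx <- as.integer(sub("mol_", "", lib$truths$molecule_id[k]))
  for (t in seq_along(k)) {
    s <- fr$sequence[frag_idx[t]]
    hit <- find_hairpin(s, pro$min_stem, pro$max_fill, pro$min_loop)
    expect_identical(lib$molecules$sequence[k[t]],
                     form_artifact(s, hit["i"], hit["j"], hit["m"]))
    expect_equal(lib$truths$artifact_len[k[t]],
                 as.integer(hit["i"] + hit["m"]))
  }
  # duplicates point at their originals and share the sequence
  dups <- which(!orig)
  if (length(dups)) {
    d <- dups[1]
    o <- match(lib$truths$duplicate_of[d], lib$truths$molecule_id)
    expect_identical(lib$molecules$sequence[d], lib$molecules$sequence[o])
  }
})

test_that("sequencing emits molecule + adapter read-through and round-trips", {
  g <- generate_genome(10000, 0.45, seed = 316)
  fr <- draw_fragments(g, 400, mean_len = 60, seed = 317)
  lib <- build_library(fr, library_protocol("forked_AT"), seed = 318)
  sq <- sequence_library(lib, read_len = 100L, error_rate = 0, seed = 319)
  ad <- illumina_adapters()
  short <- which(lib$molecules$length < 100 - nchar(ad$p7))[1]
  expected <- paste0(lib$molecules$sequence[short], ad$p7)
  expect_identical(substr(sq$r1$sequence[short], 1, nchar(expected)),
                   expected)
  # error-free collapse reconstructs every molecule exactly
  col <- collapse_library(sq)
  m <- match(col$id, lib$molecules$molecule_id)
  expect_identical(col$sequence, lib$molecules$sequence[m])

  # empirical substitution rate matches error_rate
  sq2 <- sequence_library(lib, read_len = 100L, error_rate = 0.01,
                          seed = 320)
  r0 <- sq$r1$sequence; r1 <- sq2$r1$sequence
  mm <- mapply(function(a, b) {
    ab <- charToRaw(a); bb <- charToRaw(b)
    keep <- ab != charToRaw(strrep("N", length(ab)))
    c(sum(ab[keep] != bb[keep]), sum(keep))
  }, r0, r1)
  rate <- sum(mm[1, ]) / sum(mm[2, ])
  expect_lt(abs(rate - 0.01), 3 * sqrt(0.01 * 0.99 / sum(mm[2, ])))
})

test_that("simulation is byte-deterministic under one seed", {
  a <- simulate_library(300, seed = 321)
  b <- simulate_library(300, seed = 321)
  expect_identical(a$r1, b$r1)
  expect_identical(a$r2, b$r2)
  expect_identical(a$truths, b$truths)
  c2 <- simulate_library(300, seed = 322)
  expect_false(identical(a$r1$sequence, c2$r1$sequence))
})
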