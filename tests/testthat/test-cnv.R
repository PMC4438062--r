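test_that("filter_segments applies the size/probe/LOH rules disjunctively", {
  map <- hand_map()
  seg <- rbind(
    seg_row("chr1", 0, 200, "gain", n_probes = 60),           # below min size
    seg_row("chr1", 1000, 1300, "gain", n_probes = 40),       # few probes
    seg_row("chr1", 2000, 2300, "gain", n_probes = 40, recurrent = TRUE),
    seg_row("chr1", 3000, 3500, "LOH", n_probes = 10),        # LOH < 3 Mb
    seg_row("chr1", 500, 900, "loss", n_probes = 80))
  # thresholds scaled to the 4 kb toy chromosome
  p <- hand_profile(seg, map = map)
  f <- filter_segments(p, min_size_bp = 300, min_probes = 50,
                       min_loh_bp = 600)
  expect_setequal(f$segments$start, c(2000, 500))   # recurrent kept, loss kept
  expect_true(all(f$segments$state %in% c("gain", "loss")))
  # idempotent
  f2 <- filter_segments(f, min_size_bp = 300, min_probes = 50,
                        min_loh_bp = 600)
  expect_identical(f$segments, f2$segments)
})

test_that("filter thresholds use the published defaults", {
  map <- generate_genome_map(1, 10, 2, chrom_length = 1e7, seed = 3)
  seg <- rbind(
    seg_row("chr1", 0, 9e4, "gain", n_probes = 60),        # 90 kb -> dropped
    seg_row("chr1", 1e5, 2.5e5, "gain", n_probes = 40),    # 40 probes -> dropped
    seg_row("chr1", 3e5, 2e6, "gain", n_probes = 60),      # passes
    seg_row("chr1", 2e6, 5.1e6, "LOH", n_probes = 10),     # 3.1 Mb -> kept
    seg_row("chr1", 6e6, 8.9e6, "LOH", n_probes = 10))     # 2.9 Mb -> dropped
  f <- filter_segments(cn_profile("c", seg, map))
  expect_setequal(f$segments$start, c(3e5, 2e6))
})

test_that("cnv_exclusion drops overlapping segments unless recurrent", {
  map <- hand_map()
  seg <- rbind(seg_row("chr1", 0, 900, "gain"),
               seg_row("chr1", 1000, 1900, "gain", recurrent = TRUE),
               seg_row("chr1", 2500, 3400, "gain"))
  excl <- data.frame(chrom = "chr1", start = c(800, 1800), end = c(1000, 2000))
  f <- filter_segments(hand_profile(seg, map = map), min_size_bp = 100,
                       min_probes = 1, min_loh_bp = 100,
                       cnv_exclusion = excl)
  expect_setequal(f$segments$start, c(1000, 2500))
})

test_that("macro_aberrations requires full-band coverage by one state", {
  map <- hand_map()
  # exactly one band
  m1 <- macro_aberrations(hand_profile(seg_row("chr1", 0, 1000, "gain"),
                                       map = map))
  expect_equal(m1, data.frame(chrom = "chr1", band = "1p2", state = "gain"))
  # 99% of a band is not enough
  m2 <- macro_aberrations(hand_profile(seg_row("chr1", 0, 990, "gain"),
                                       map = map))
  expect_equal(nrow(m2), 0)
  # two adjacent segments jointly covering one band emit it once
  m3 <- macro_aberrations(hand_profile(
    rbind(seg_row("chr1", 0, 400, "gain"), seg_row("chr1", 400, 1100, "gain")),
    map = map))
  expect_equal(m3$band, "1p2")
  expect_equal(nrow(m3), 1)
  # a multi-band segment reports every covered band
  m4 <- macro_aberrations(hand_profile(seg_row("chr1", 0, 2000, "loss"),
                                       map = map))
  expect_setequal(m4$band, c("1p2", "1p1"))
})

test_that("macro_aberrations is invariant under segment splitting", {
  map <- tiny_map()
  band <- map$cytobands[3, ]
  whole <- hand_profile(seg_row(band$chrom, band$start, band$end, "gain"),
                        condition = "c", map = map)
  mid <- round((band$start + band$end) / 2)
  split <- hand_profile(rbind(
    seg_row(band$chrom, band$start, mid, "gain"),
    seg_row(band$chrom, mid, band$end, "gain")), condition = "c", map = map)
  expect_equal(macro_aberrations(whole), macro_aberrations(split))
})

test_that("gene_cn_status follows the majority-overlap rule", {
  map <- hand_map()
  # g00001 spans [100,200): fully inside gain; g00003 [1100,1200): 60% loss
  seg <- rbind(seg_row("chr1", 0, 1000, "gain"),
               seg_row("chr1", 1100, 1160, "loss"),
               seg_row("chr1", 3000, 4000, "LOH"))
  st <- gene_cn_status(hand_profile(seg, map = map), map)
  expect_equal(nrow(st), universe_size(map))
  get <- function(g) st$state[st$gene_id == g]
  expect_equal(get("g00001"), "gain")
  expect_equal(get("g00003"), "loss")    # 60% of span in loss
  expect_equal(get("g00005"), "neutral") # no overlapping segment
  # 40% overlap is not a majority
  seg2 <- seg_row("chr1", 1100, 1140, "loss")
  st2 <- gene_cn_status(hand_profile(seg2, map = map), map)
  expect_equal(st2$state[st2$gene_id == "g00003"], "neutral")
  # LOH flagged separately, never overriding state
  expect_true(all(st$loh[st$gene_id %in% c("g00007", "g00008")]))
  expect_equal(get("g00007"), "neutral")
})

test_that("aberrant_fraction computes percentages over the universe", {
  st <- structure(data.frame(gene_id = sprintf("g%03d", 1:100),
                             state = rep(c("gain", "loss", "neutral"),
                                         c(43, 5, 52)),
                             loh = FALSE),
                  class = c("gene_cn_status", "data.frame"))
  f <- aberrant_fraction(st)
  expect_equal(unname(f), c(43, 5, 48))
  all_neutral <- structure(data.frame(gene_id = "g1", state = "neutral",
                                      loh = FALSE),
                           class = c("gene_cn_status", "data.frame"))
  expect_equal(unname(aberrant_fraction(all_neutral)), c(0, 0, 0))
})

test_that("cn_delta mirrors the worked early/late arithmetic", {
  mk <- function(states) {
    structure(data.frame(gene_id = sprintf("g%04d", seq_along(states)),
                         state = states, loh = FALSE),
              class = c("gene_cn_status", "data.frame"))
  }
  a <- mk(rep("neutral", 1000))
  b_states <- rep("neutral", 1000)
  b_states[1:44] <- "gain"                   # 44 neutral -> gain
  a$state[45:121] <- "gain"                  # 77 gain -> neutral
  b <- mk(b_states)
  d <- cn_delta(a, b)
  expect_equal(unname(d$summary), c(4.4, 7.7, 12.1))
  # identical profiles change nothing
  expect_equal(unname(cn_delta(a, a)$summary), c(0, 0, 0))
  # antisymmetry of the change classes
  rev <- cn_delta(b, a)
  expect_equal(d$per_gene$gene_id[d$per_gene$delta == "gain-change"],
               rev$per_gene$gene_id[rev$per_gene$delta == "loss-change"])
  expect_error(cn_delta(a, mk(rep("neutral", 10))), "universe")
})

test_that("synthetic whole-band events round-trip through the callers", {
  map <- tiny_map()
  des <- one_system_design()
  band <- map$cytobands$band[2]
  ev <- rbind(
    data.frame(condition = "LM5_late", band = band, chrom = NA, start = NA,
               end = NA, state = "gain", n_probes = 300),
    data.frame(condition = "LM5_late", band = NA, chrom = "chr2", start = 0,
               end = 5e4, state = "loss", n_probes = 20))  # sub-threshold
  cn <- generate_cn_profiles(map, des, ev, seed = 2)
  f <- filter_segments(cn$profiles[["LM5_late"]])
  expect_equal(nrow(f$segments), 1)           # sub-threshold segment removed
  m <- macro_aberrations(f)
  expect_equal(m$band, band)
  expect_equal(m$state, "gain")
})
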