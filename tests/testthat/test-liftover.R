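# Chain parsing and coordinate lifting

write_chain <- function(lines) {
  path <- tempfile(fileext = ".chain")
  writeLines(lines, path)
  path
}

test_that("a single identity chain parses and lifts positions unchanged", {
  cs <- parse_chain(write_chain(c(
    "chain 100 chrA 1000 + 0 100 chrB 1000 + 0 100 1", "100", ""
  )))
  expect_equal(length(cs$chains), 1L)
  expect_equal(nrow(cs$chains[[1]]$blocks), 1L)
  res <- lift_position(cs, "chrA", 42)
  expect_equal(res$status, "mapped")
  expect_equal(res$pos, 42)
  expect_false(res$strand_flip)
})

test_that("arithmetically inconsistent chains are format errors", {
  expect_error(parse_chain(write_chain(c(
    "chain 100 chrA 1000 + 0 100 chrB 1000 + 0 100 1", "90", ""
  ))), "format error.*1")
  expect_error(parse_chain(write_chain(c(
    "chain 100 chrA 1000 + 0 100 chrB 1000 + 0 95 1", "50 10 0", "40", ""
  ))), "query span")
})

test_that("positions in dt gaps report gap; block offsets map exactly", {
  # two blocks of 50 with a 10 bp target gap between them
  cs <- parse_chain(write_chain(c(
    "chain 100 chrA 1000 + 0 110 chrB 1000 + 0 100 1", "50 10 0", "50", ""
  )))
  expect_equal(lift_position(cs, "chrA", 55)$status, "gap")
  r <- lift_position(cs, "chrA", 65)
  expect_equal(r$status, "mapped")
  expect_equal(r$pos, 55)
  # outside any chain span
  expect_equal(lift_position(cs, "chrA", 500)$status, "unmapped")
  expect_equal(lift_position(cs, "chrZ", 10)$status, "unmapped")
})

test_that("lifting agrees with the per-base expansion oracle, both strands", {
  set.seed(101)
  for (rep in 1:6) {
    # random small chain: blocks and gaps on a <=10 kb span
    nb <- sample(2:6, 1)
    size <- sample(50:400, nb, replace = TRUE)
    dt <- c(sample(0:80, nb - 1, replace = TRUE), 0)
    dq <- c(sample(0:80, nb - 1, replace = TRUE), 0)
    t_start <- sample(0:500, 1)
    t_end <- t_start + sum(size) + sum(dt)
    q_start <- sample(0:500, 1)
    q_end <- q_start + sum(size) + sum(dq)
    q_strand <- sample(c("+", "-"), 1)
    q_size <- q_end + sample(100:1000, 1)
    lines <- c(sprintf("chain 99 chrA 20000 + %d %d chrB %d %s %d %d 1",
                       t_start, t_end, q_size, q_strand, q_start, q_end),
               paste(size[-nb], dt[-nb], dq[-nb]),
               as.character(size[nb]), "")
    cs <- parse_chain(write_chain(lines))
    oracle <- oracle_expand_chain(cs$chains[[1]])
    pos <- t_start:(t_end - 1)
    got <- lift_position(cs, "chrA", pos)
    expect_equal(got$status, oracle$status)
    expect_equal(got$pos, oracle$qpos)
    # within-block lifts are affine and order-reversing iff strand flips
    mapped <- got$pos[got$status == "mapped"]
    blk <- lift_position(cs, "chrA", t_start + 0:(size[1] - 1))
    expect_true(all(abs(diff(blk$pos)) == 1))
    if (q_strand == "-") {
      expect_true(all(diff(blk$pos) == -1))
    } else {
      expect_true(all(diff(blk$pos) == 1))
    }
  }
})

test_that("the highest-scoring covering chain wins", {
  cs <- parse_chain(write_chain(c(
    "chain 50 chrA 1000 + 0 100 chrB 1000 + 0 100 low", "100", "",
    "chain 900 chrA 1000 + 50 150 chrC 1000 + 500 600 high", "100", ""
  )))
  r1 <- lift_position(cs, "chrA", 10)   # only low chain covers
  expect_equal(r1$chain_id, "low")
  r2 <- lift_position(cs, "chrA", 60)   # both cover; high score wins
  expect_equal(r2$chain_id, "high")
  expect_equal(r2$pos, 510)
})

test_that("overlap index agrees with a linear scan on synthetic chains", {
  cfg <- sim_config(n_genes = 60, genes_per_chrom = 20, seed = 5)
  geno <- simulate_genome_pair(cfg)
  cs <- parse_chain(write_chain(geno$chain_lines))
  set.seed(9)
  for (i in 1:20) {
    chrom <- sample(unique(cs$index$t_name), 1)
    start <- sample(0:50000, 1)
    end <- start + sample(1:5000, 1)
    got <- sort(chains_overlapping(cs, chrom, start, end))
    want <- which(vapply(cs$chains, function(ch) {
      ch$t_name == chrom && ch$t_start < end && ch$t_end > start
    }, TRUE))
    expect_equal(got, want)
  }
})

test_that("events lift through identity and flipped chains correctly", {
  ev <- make_events(3, chrom = "chrA", start0 = 100, spacing = 2000)
  # identity chain: lifted event equals input up to chromosome rename
  cs <- parse_chain(write_chain(c(
    "chain 10 chrA 100000 + 0 100000 chrB 100000 + 0 100000 1", "100000", ""
  )))
  lf <- lift_event(cs, ev)
  expect_equal(nrow(lf$failures), 0L)
  expect_equal(lf$lifted$upstream_end, ev$upstream_end)
  expect_equal(lf$lifted$target_start, ev$target_start)
  expect_equal(lf$lifted$chrom, rep("chrB", 3))
  # strand-flip chain: length preserved, strand toggled, order re-normalised
  csf <- parse_chain(write_chain(c(
    "chain 10 chrA 100000 + 0 100000 chrB 100000 - 0 100000 1", "100000", ""
  )))
  lff <- lift_event(csf, ev)
  expect_equal(nrow(lff$failures), 0L)
  expect_equal(lff$lifted$target_end - lff$lifted$target_start,
               ev$target_end - ev$target_start)
  expect_equal(lff$lifted$strand, rep("-", 3))
  expect_equal(validate_events(lff$lifted), lff$lifted)
  # flip is an involution on the boundary tuple: lifting back through the
  # inverse flip chain restores the original coordinates
  csb <- parse_chain(write_chain(c(
    "chain 10 chrB 100000 + 0 100000 chrA 100000 - 0 100000 1", "100000", ""
  )))
  back <- lift_event(csb, lff$lifted)$lifted
  back <- back[match(ev$event_id, back$event_id), ]
  expect_equal(back$upstream_end, ev$upstream_end)
  expect_equal(back$target_start, ev$target_start)
  expect_equal(back$target_end, ev$target_end)
  expect_equal(back$downstream_start, ev$downstream_start)
  expect_equal(back$strand, ev$strand)
})

test_that("events straddling gaps yield failure records with gap status", {
  ev <- make_events(1, chrom = "chrA", start0 = 100)
  # gap [550, 600) covers target_start = 600? target_start = 600
  # layout: u=100..? make_events: upstream_end=100, target_start=600,
  # target_end=700, downstream_start=1200; put a dt gap over 600
  cs <- parse_chain(write_chain(c(
    "chain 10 chrA 100000 + 0 100000 chrB 100000 + 0 99990 1",
    "595 10 0", "99395", ""
  )))
  lf <- lift_event(cs, ev)
  expect_equal(nrow(lf$lifted), 0L)
  expect_equal(lf$failures$target_start_status, "gap")
  expect_equal(lf$failures$reason, "boundary not mapped")
})

test_that("round trip through a chain and its synthetic inverse is identity", {
  cfg <- sim_config(n_genes = 40, genes_per_chrom = 20, flip_fraction = 0,
                    seed = 13)
  geno <- simulate_genome_pair(cfg)
  cs <- parse_chain(write_chain(geno$chain_lines))
  # build the inverse chain set by swapping t and q roles block-wise
  inv_lines <- character(0)
  for (ch in cs$chains) {
    head <- sprintf("chain %d %s %d + %d %d %s %d + %d %d %s",
                    as.integer(ch$score), ch$q_name, as.integer(ch$q_size),
                    as.integer(ch$q_start), as.integer(ch$q_end),
                    ch$t_name, as.integer(ch$t_size),
                    as.integer(ch$t_start), as.integer(ch$t_end),
                    ch$id)
    nb <- nrow(ch$blocks)
    body <- if (nb > 1) {
      c(paste(ch$blocks$size[-nb], ch$blocks$dq[-nb], ch$blocks$dt[-nb]),
        as.character(ch$blocks$size[nb]))
    } else {
      as.character(ch$blocks$size)
    }
    inv_lines <- c(inv_lines, head, body, "")
  }
  inv <- parse_chain(write_chain(inv_lines))
  set.seed(3)
  idx <- cs$index
  for (i in 1:200) {
    row <- idx[sample.int(nrow(idx), 1), ]
    p <- sample(row$t_start:(row$t_end - 1), 1)
    fwd <- lift_position(cs, row$t_name, p)
    if (fwd$status != "mapped") next
    back <- lift_position(inv, fwd$chrom, fwd$pos)
    expect_equal(back$status, "mapped")
    expect_equal(back$pos, p)
  }
})

test_that("position lifting matches rtracklayer::liftOver on a shared chain", {
  skip_if_not_installed("rtracklayer")
  skip_if_not_installed("GenomicRanges")
  cfg <- sim_config(n_genes = 40, genes_per_chrom = 20, seed = 21)
  geno <- simulate_genome_pair(cfg)
  path <- write_chain(geno$chain_lines)
  cs <- parse_chain(path)
  rt_chain <- rtracklayer::import.chain(path)
  set.seed(4)
  idx <- cs$index
  for (i in 1:100) {
    row <- idx[sample.int(nrow(idx), 1), ]
    p <- sample(row$t_start:(row$t_end - 1), 1)
    mine <- lift_position(cs, row$t_name, p)
    gr <- GenomicRanges::GRanges(row$t_name,
                                 IRanges::IRanges(p + 1, p + 1))
    hit <- rtracklayer::liftOver(gr, rt_chain)[[1]]
    if (mine$status == "mapped") {
      expect_equal(length(hit), 1L)
      expect_equal(GenomicRanges::start(hit) - 1L, as.integer(mine$pos))
      expect_equal(as.character(GenomicRanges::seqnames(hit)), mine$chrom)
    } else {
      expect_equal(length(hit), 0L)
    }
  }
})
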