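# Shared fixtures: everything is built in code, no binary data.

# A toy genome with round numbers: 100 Mb chromosome, centromere at 40 Mb
# (p arm 40 Mb, q arm 60 Mb), plus a second chromosome.
toy_genome <- function() {
  data.frame(chrom = c("chr1", "chr2"),
             length = c(100e6, 80e6),
             centromere = c(40e6, 30e6),
             stringsAsFactors = FALSE)
}

toy_segment <- function(start, end, seg_mean, sample = "S1", chrom = "chr1") {
  data.frame(sample = sample, chrom = chrom, start = start, end = end,
             seg_mean = seg_mean, stringsAsFactors = FALSE)
}

# Joins closing a planted triangle over three amplified segments
triangle_fixture <- function() {
  segs <- rbind(toy_segment(10e6, 11e6, 2.5),
                toy_segment(20e6, 20.5e6, 2.8),
                toy_segment(50e6, 51e6, 2.2))
  joins <- data.frame(
    chrom1 = "chr1", pos1 = c(11e6, 20.5e6, 51e6), strand1 = "+",
    chrom2 = "chr1", pos2 = c(20e6, 50e6, 10e6), strand2 = "-",
    name = c("j1", "j2", "j3"), stringsAsFactors = FALSE)
  joins$orientation <- orientation_class(joins$strand1, joins$strand2)
  list(segments = segs, joins = joins)
}

# Brute-force Fisher oracle: enumerate all tables with the observed margins.
fisher_oracle <- function(tab, sidedness = "two.sided") {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(c1, r1)
  prob <- vapply(support, function(x) {
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(r1 + r2, c1))
  }, 0)
  p_obs <- prob[match(a, support)]
  switch(sidedness,
         two.sided = sum(prob[prob <= p_obs * (1 + 1e-7)]),
         greater = sum(prob[support >= a]),
         less = sum(prob[support <= a]))
}

# Independent exact multinomial uniformity oracle (4 classes)
multinom_oracle <- function(counts) {
  n <- sum(counts)
  p_obs <- dmultinom(counts, prob = rep(0.25, 4))
  total <- 0
  for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
    d <- n - a - b - cc
    pr <- dmultinom(c(a, b, cc, d), prob = rep(0.25, 4))
    if (pr <= p_obs * (1 + 1e-9)) total <- total + pr
  }
  min(1, total)
}
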