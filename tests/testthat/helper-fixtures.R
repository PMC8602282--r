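# Small in-code fixtures shared across tests.

# a 3-sample, 4-genus integer count cohort with loads and copy numbers
toyCohort <- function() {
  counts <- rbind(
    s1 = c(gA = 40L, gB = 30L, gC = 20L, gD = 10L),
    s2 = c(gA = 10L, gB = 60L, gC = 25L, gD = 5L),
    s3 = c(gA = 55L, gB = 5L, gC = 30L, gD = 10L)
  )
  MicrobiomeCohort(counts,
                   participant = c("p1", "p1", "p2"),
                   day = c(0L, 1L, 0L),
                   unit = "reads",
                   sample_id = rownames(counts),
                   load = c(1e11, 1.5e11, 0.8e11),
                   moisture = c(70, 75, 68),
                   copy_numbers = c(gA = 2, gB = 4, gC = 1, gD = 5))
}

# write a small cohort to TSV files and return the paths
writeToyFiles <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  counts <- data.frame(sample_id = c("s1", "s2", "s3"),
                       gA = c(40L, 10L, 55L), gB = c(30L, 60L, 5L),
                       gC = c(20L, 25L, 30L), gD = c(10L, 5L, 10L))
  meta <- data.frame(sample_id = c("s1", "s2", "s3"),
                     participant_id = c("p1", "p1", "p2"),
                     day = c(0L, 1L, 0L),
                     load = c(1e11, 1.5e11, NA),
                     moisture = c(70, 75, 68))
  diet <- data.frame(participant_id = "p1", day = 0:1,
                     carb_g = c(200, 250), protein_g = c(80, 70),
                     fat_g = c(60, 65), fiber_g = c(20, 25),
                     sodium_g = c(3, 2))
  cn <- data.frame(genus_id = c("gA", "gB", "gC"),
                   copy_number = c(2, 4, 1))
  paths <- list(counts = file.path(dir, "counts.tsv"),
                meta = file.path(dir, "meta.tsv"),
                diet = file.path(dir, "diet.tsv"),
                cn = file.path(dir, "cn.tsv"))
  write.table(counts, paths$counts, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(meta, paths$meta, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(diet, paths$diet, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cn, paths$cn, sep = "\t", quote = FALSE, row.names = FALSE)
  paths
}

# brute-force one-way ANOVA variance components (independent oracle)
bruteICC <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  ni <- as.numeric(table(groups))
  N <- sum(ni)
  gmean <- mean(values)
  means <- tapply(values, groups, mean)
  msb <- sum(ni * (means - gmean)^2) / (k - 1)
  msw <- sum(unlist(lapply(levels(groups), function(g)
    (values[groups == g] - means[g])^2))) / (N - k)
  k0 <- (N - sum(ni^2) / N) / (k - 1)
  va <- (msb - msw) / k0
  va / (va + msw)
}

# naive double-loop Bray-Curtis (independent oracle)
bruteBC <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
  out
}

adjRand <- function(a, b) mbtemporal:::.ari(a, b)
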