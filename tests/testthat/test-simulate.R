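test_that("pedigree structure is forced by the mating design", {
  ped <- build_pedigree(20, 10, 15)
  expect_equal(nrow(ped), 3220)
  off <- ped[ped$generation != "founder", ]
  expect_equal(length(unique(off$sire)), 20)             # half-sib families
  expect_equal(nrow(unique(off[c("sire", "dam")])), 200) # full-sib families
  expect_true(all(table(off$dam) == 15))
  expect_true(all(table(off$sire) == 150))

  expect_equal(nrow(build_pedigree(1, 1, 1)), 3)
  expect_equal(nrow(build_pedigree(2, 3, 4)), 32)
  # parents appear before offspring, founders have unknown parents
  expect_true(all(match(off$sire, ped$id) < match(off$id, ped$id)))
  fo <- ped[ped$generation == "founder", ]
  expect_true(all(is.na(fo$sire) & is.na(fo$dam)))
  expect_error(build_pedigree(0, 1, 1), "positive")
  expect_error(build_pedigree(2, -1, 3), "positive")
})

test_that("meiosis follows the Haldane map function", {
  # two loci 1 Morgan apart on one chromosome; parent heterozygous in
  # coupling phase, so a recombinant gamete mixes the two strands
  map <- data.frame(snp_id = c("a", "b"), chromosome = c(1L, 1L),
                    position = c(0, 1))
  attr(map, "chrom_length") <- 1
  class(map) <- c("gs_map", "data.frame")
  n <- 1e5
  set.seed(42)
  gam <- gsbench:::cpp_drop_gametes(
    matrix(c(1L, 1L), 1), matrix(c(0L, 0L), 1), rep(1L, n),
    map$position, map$chromosome, 1)
  rec <- mean(gam[, 1] != gam[, 2])
  theo <- (1 - exp(-2)) / 2
  se <- sqrt(theo * (1 - theo) / n)
  expect_lt(abs(rec - theo), 3 * se)

  # coincident loci are always co-inherited
  map0 <- map
  map0$position <- c(0.3, 0.3)
  gam0 <- gsbench:::cpp_drop_gametes(
    matrix(c(1L, 1L), 1), matrix(c(0L, 0L), 1), rep(1L, 2000),
    map0$position, map0$chromosome, 1)
  expect_true(all(gam0[, 1] == gam0[, 2]))

  # single locus: Mendelian sampling of either parental allele
  map1 <- map[1, ]
  attr(map1, "chrom_length") <- 1
  class(map1) <- c("gs_map", "data.frame")
  set.seed(7)
  alleles <- replicate(4000, meiose(list(pat = 1L, mat = 0L), map1))
  expect_lt(abs(mean(alleles) - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("founder genomes carry distance-decaying LD and are reproducible", {
  map <- make_map(snps_per_chrom = 250, n_chrom = 2)
  f1 <- simulate_founder_genomes(map, 80, ne = 60, n_hist_generations = 60,
                                 seed = 9)
  f2 <- simulate_founder_genomes(map, 80, ne = 60, n_hist_generations = 60,
                                 seed = 9)
  expect_identical(f1$hap_pat, f2$hap_pat)
  expect_identical(f1$hap_mat, f2$hap_mat)
  f3 <- simulate_founder_genomes(map, 80, ne = 60, n_hist_generations = 60,
                                 seed = 10)
  expect_false(identical(f1$hap_pat, f3$hap_pat))

  Z <- dosages(f1)
  maf <- pmin(colMeans(Z) / 2, 1 - colMeans(Z) / 2)
  expect_true(all(maf >= 0.01))
  keep <- which(maf >= 0.05 & map$chromosome == 1)
  r2_at <- function(min_d, max_d) {
    set.seed(1)
    pairs <- t(combn(sample(keep, min(60, length(keep))), 2))
    d <- abs(map$position[pairs[, 1]] - map$position[pairs[, 2]])
    sel <- d >= min_d & d <= max_d
    mean(cor(Z[, pairs[sel, 1], drop = FALSE],
             Z[, pairs[sel, 2], drop = FALSE])[cbind(seq_len(sum(sel)),
                                                     seq_len(sum(sel)))]^2)
  }
  expect_gt(r2_at(0, 0.02), r2_at(0.4, 1))

  # no history: loci are independent apart from sampling noise
  f0 <- simulate_founder_genomes(map, 200, ne = 60, n_hist_generations = 0,
                                 seed = 2)
  Z0 <- dosages(f0)
  set.seed(3)
  far <- which(map$chromosome == 1)
  pr <- cbind(sample(far, 40), sample(which(map$chromosome == 2), 40))
  rr <- abs(diag(cor(Z0[, pr[, 1]], Z0[, pr[, 2]])))
  expect_lt(mean(rr), 0.12)
})

test_that("gene dropping is Mendelian and dosages match haplotypes", {
  sim <- small_sim()
  g <- sim$geno
  ped <- sim$pedigree
  expect_equal(unname(dosages(g)), g$hap_pat + g$hap_mat,
               ignore_attr = TRUE)
  off <- which(ped$generation != "founder")
  for (i in off[c(1, 5, 20)]) {
    s <- match(ped$sire[i], ped$id)
    d <- match(ped$dam[i], ped$id)
    expect_true(all(g$hap_pat[i, ] == g$hap_pat[s, ] |
                      g$hap_pat[i, ] == g$hap_mat[s, ]))
    expect_true(all(g$hap_mat[i, ] == g$hap_pat[d, ] |
                      g$hap_mat[i, ] == g$hap_mat[d, ]))
  }
})

test_that("architecture has the 1/2/2/1/2 layout with the chr1 QTL largest", {
  sim <- small_sim()
  q <- sim$arch$qtls
  expect_equal(as.vector(table(q$chromosome)), c(1, 2, 2, 1, 2))
  expect_equal(sum(q$kind == "imprinted"), 1)
  expect_equal(q$chromosome[q$kind == "imprinted"], 4)
  expect_equal(sum(q$kind == "epistatic"), 2)
  expect_true(all(q$chromosome[q$kind == "epistatic"] == 5))
  for (cc in 2:3) {
    pos <- q$position[q$chromosome == cc]
    expect_lt(abs(diff(pos)), 0.2)
  }
  # single-locus additive variances recomputed from effects and frequencies
  v <- ifelse(q$kind == "additive", q$effect^2 * 2 * q$freq * (1 - q$freq),
              ifelse(q$kind == "imprinted",
                     q$effect^2 * q$freq * (1 - q$freq), 0))
  expect_equal(which.max(v), 1L)
  expect_equal(sim$arch$sigma2_e,
               sim$arch$sigma2_g * 0.7 / 0.3, tolerance = 1e-12)
  # common rescaling hits the genetic variance target among founders
  founders <- which(sim$pedigree$generation == "founder")
  gsub <- make_test_geno(sim$map, sim$geno$hap_pat[founders, ],
                         sim$geno$hap_mat[founders, ])
  expect_equal(var(compute_tbv(gsub, sim$arch)), sim$arch$sigma2_g,
               tolerance = 1e-8)
})

test_that("TBV matches per-kind closed forms and the 9-cell epistasis oracle", {
  map <- make_map(snps_per_chrom = 1, n_chrom = 5)
  # single additive QTL, p = 0.5: TBV in {-a, 0, a}
  hp <- matrix(c(0L, 0L, 1L), 3, 5)
  hm <- matrix(c(0L, 1L, 1L), 3, 5)
  g <- make_test_geno(map, hp, hm)
  arch <- make_test_arch(map, loci = 1, kinds = "additive", effects = 2,
                         freqs = 0.5)
  expect_equal(unname(compute_tbv(g, arch)), c(-2, 0, 2))

  # all-zero effects give identically zero TBV
  arch0 <- make_test_arch(map, loci = c(1, 2), kinds = rep("additive", 2),
                          effects = c(0, 0), freqs = c(0.5, 0.3))
  expect_true(all(compute_tbv(g, arch0) == 0))

  # imprinted QTL reads the paternal allele only
  archi <- make_test_arch(map, loci = 2, kinds = "imprinted", effects = 1.5,
                          freqs = 0.4)
  expect_equal(unname(compute_tbv(g, archi)),
               1.5 * (hp[, 2] - 0.4))
  gd <- g
  gd$dosage <- dosages(g)
  gd$hap_pat <- gd$hap_mat <- NULL
  expect_error(compute_tbv(gd, archi), "origin")

  # epistatic pair: marginals against brute-force Hardy-Weinberg enumeration
  set.seed(1)
  tab <- matrix(rnorm(9), 3, 3)
  p1 <- 0.3
  p2 <- 0.6
  arche <- make_test_arch(map, loci = c(3, 4), kinds = rep("epistatic", 2),
                          effects = c(1, 1), freqs = c(p1, p2),
                          epi_table = tab)
  hw <- function(p) c((1 - p)^2, 2 * p * (1 - p), p^2)
  exp_m1 <- sapply(0:2, function(z1) sum(hw(p2) * tab[z1 + 1, ]))
  exp_m2 <- sapply(0:2, function(z2) sum(hw(p1) * tab[, z2 + 1]))
  exp_m1 <- exp_m1 - sum(hw(p1) * exp_m1)
  exp_m2 <- exp_m2 - sum(hw(p2) * exp_m2)
  # all 9 two-locus genotypes
  combos <- expand.grid(z1 = 0:2, z2 = 0:2)
  hp9 <- cbind(0L, 0L, pmin(combos$z1, 1L), pmin(combos$z2, 1L), 0L)
  hm9 <- cbind(0L, 0L, pmax(combos$z1 - 1L, 0L), pmax(combos$z2 - 1L, 0L), 0L)
  g9 <- make_test_geno(map, hp9, hm9)
  expect_equal(unname(compute_tbv(g9, arche)),
               exp_m1[combos$z1 + 1] + exp_m2[combos$z2 + 1],
               tolerance = 1e-12)
})

test_that("phenotyping covers the leading two thirds of each family", {
  sim <- small_sim()
  ped <- sim$pedigree
  ph <- sim$pheno
  off <- ped$generation != "founder"
  expect_equal(sum(ph$phenotyped), 12 * ceiling(2 / 3 * 8)) # 12 families x 6
  expect_true(all(!ph$phenotyped[!off]))
  fam <- split(seq_len(nrow(ped))[off],
               interaction(ped$sire[off], ped$dam[off], drop = TRUE))
  for (f in fam) {
    expect_equal(ph$phenotyped[sort(f)],
                 rep(c(TRUE, FALSE), c(6, 2)))
  }
  expect_error(
    simulate_phenotypes(ph$tbv, sim$arch, ped, sim$geno,
                        phenotyped_fraction = 0), "0, 1")

  # zero residual variance: phenotype equals the full genotypic value
  arch0 <- sim$arch
  arch0$sigma2_resid <- 1e-24
  p0 <- simulate_phenotypes(ph$tbv, arch0, ped, sim$geno, seed = 1)
  gv <- gsbench:::genotypic_value(sim$geno, sim$arch)
  expect_equal(p0$y[p0$phenotyped], unname(gv[p0$phenotyped]),
               tolerance = 1e-6)
})

test_that("the whole dataset is reproducible from its master seed", {
  a <- sim_gsdata(n_sires = 2, dams_per_sire = 2, offspring_per_dam = 4,
                  snps_per_chrom = 30, ne = 20, n_hist_generations = 10,
                  seed = 5)
  b <- sim_gsdata(n_sires = 2, dams_per_sire = 2, offspring_per_dam = 4,
                  snps_per_chrom = 30, ne = 20, n_hist_generations = 10,
                  seed = 5)
  expect_identical(a$Z, b$Z)
  expect_identical(a$pheno$y, b$pheno$y)
  expect_identical(a$arch$qtls, b$arch$qtls)
  d <- sim_gsdata(n_sires = 2, dams_per_sire = 2, offspring_per_dam = 4,
                  snps_per_chrom = 30, ne = 20, n_hist_generations = 10,
                  seed = 6)
  expect_false(identical(a$Z, d$Z))
})

test_that("realised heritability tracks the target across replicates", {
  r <- sapply(1:5, function(s) {
    sim <- sim_gsdata(n_sires = 8, dams_per_sire = 5, offspring_per_dam = 10,
                      snps_per_chrom = 150, ne = 50, n_hist_generations = 40,
                      seed = 100 + s)
    ph <- sim$pheno[sim$pheno$phenotyped, ]
    var(ph$tbv) / var(ph$y)
  })
  expect_gt(mean(r), 0.2)
  expect_lt(mean(r), 0.4)
})
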