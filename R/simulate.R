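#' Build a balanced hierarchical half-sib/full-sib pedigree
#'
#' Constructs a two-generation pedigree in which each sire is mated to
#' `dams_per_sire` dams and each dam produces `offspring_per_dam` offspring,
#' so the offspring of one dam form a full-sib family and the offspring of
#' one sire form a half-sib family. The default scale of the simulator
#' (`20 x 10 x 15`) yields 3220 individuals: 220 founders and 3000 offspring
#' in 20 half-sib and 200 full-sib families.
#'
#' @param n_sires Number of sires (founder males).
#' @param dams_per_sire Number of dams mated to each sire.
#' @param offspring_per_dam Full-sib family size.
#' @return A `data.frame` of class `gs_pedigree` with columns `id`, `sire`,
#'   `dam` (`NA` for unknown parents) and `generation`
#'   (`"founder"`/`"offspring"`), sorted parents before offspring.
#' @examples
#' ped <- build_pedigree(2, 3, 4)
#' nrow(ped) # 2 + 6 + 24
#' @export
build_pedigree <- function(n_sires, dams_per_sire, offspring_per_dam) {
  for (v in c(n_sires, dams_per_sire, offspring_per_dam)) {
    if (length(v) != 1L || !is.finite(v) || v < 1 || v != round(v)) {
      stop("pedigree counts must be positive integers", call. = FALSE)
    }
  }
  n_dams <- n_sires * dams_per_sire
  n_off <- n_dams * offspring_per_dam
  sires <- seq_len(n_sires)
  dams <- n_sires + seq_len(n_dams)
  off <- n_sires + n_dams + seq_len(n_off)
  dam_sire <- rep(sires, each = dams_per_sire)
  off_dam <- rep(dams, each = offspring_per_dam)
  off_sire <- rep(dam_sire, each = offspring_per_dam)
  ped <- data.frame(
    id = c(sires, dams, off),
    sire = c(rep(NA_integer_, n_sires + n_dams), off_sire),
    dam = c(rep(NA_integer_, n_sires + n_dams), off_dam),
    generation = rep(c("founder", "offspring"), c(n_sires + n_dams, n_off))
  )
  class(ped) <- c("gs_pedigree", "data.frame")
  ped
}

#' Build an equally spaced SNP map
#'
#' Positions are in Morgans, 0-based from the chromosome start, with
#' `snps_per_chrom` loci per chromosome spaced `chrom_length/snps_per_chrom`
#' apart.
#'
#' @param snps_per_chrom Loci per chromosome.
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Chromosome length in Morgans.
#' @return A `data.frame` of class `gs_map` with columns `snp_id`,
#'   `chromosome`, `position`.
#' @export
make_map <- function(snps_per_chrom = 2000, n_chrom = 5, chrom_length = 1) {
  stopifnot(snps_per_chrom >= 1, n_chrom >= 1, chrom_length > 0)
  chrom <- rep(seq_len(n_chrom), each = snps_per_chrom)
  within_idx <- rep(seq_len(snps_per_chrom), n_chrom)
  map <- data.frame(
    snp_id = sprintf("C%dM%05d", chrom, within_idx),
    chromosome = chrom,
    position = (within_idx - 1) * (chrom_length / snps_per_chrom)
  )
  attr(map, "chrom_length") <- rep(chrom_length, n_chrom)
  class(map) <- c("gs_map", "data.frame")
  map
}

chrom_lengths <- function(map) {
  cl <- attr(map, "chrom_length")
  n_chrom <- max(map$chromosome)
  if (is.null(cl) || length(cl) != n_chrom) {
    # fall back: span of observed positions, at least 1 Morgan
    cl <- vapply(seq_len(n_chrom), function(cc) {
      p <- map$position[map$chromosome == cc]
      if (!length(p)) return(1)
      max(1, max(p))
    }, numeric(1))
  }
  cl
}

#' Sample one gamete from a parent by meiosis
#'
#' Crossovers follow a Haldane (no-interference) process: counts are
#' Poisson with mean equal to the chromosome length in Morgans, positions
#' uniform, and the starting parental strand is a fair coin per chromosome,
#' so the recombination fraction between loci `d` Morgans apart is
#' `(1 - exp(-2 d)) / 2`.
#'
#' Uses R's global random number stream; call `set.seed()` for
#' reproducibility.
#'
#' @param parent List with integer allele vectors `pat` and `mat` over the
#'   loci of `map`, or a 2-row matrix (rows = the two haplotypes).
#' @param map A `gs_map`.
#' @return Integer vector of gamete alleles.
#' @export
meiose <- function(parent, map) {
  if (is.matrix(parent)) parent <- list(pat = parent[1, ], mat = parent[2, ])
  stopifnot(length(parent$pat) == nrow(map), length(parent$mat) == nrow(map))
  g <- cpp_drop_gametes(
    matrix(as.integer(parent$pat), nrow = 1),
    matrix(as.integer(parent$mat), nrow = 1),
    1L, map$position, as.integer(map$chromosome), chrom_lengths(map)
  )
  g[1, ]
}

new_geno <- function(map, hap_pat, hap_mat, ids, dosage = NULL) {
  g <- list(map = map, hap_pat = hap_pat, hap_mat = hap_mat,
            ids = ids, dosage = dosage)
  class(g) <- "gs_geno"
  g
}

#' Extract the allele-dosage matrix of a genotype object
#'
#' @param geno A `gs_geno` object.
#' @param loci Optional locus (column) subset.
#' @return Numeric matrix individuals x loci with entries 0/1/2, rownames
#'   the individual ids and colnames the snp ids.
#' @export
dosages <- function(geno, loci = NULL) {
  if (!is.null(geno$dosage)) {
    Z <- geno$dosage
  } else {
    Z <- geno$hap_pat + geno$hap_mat
    storage.mode(Z) <- "double"
    dimnames(Z) <- list(as.character(geno$ids), geno$map$snp_id)
  }
  if (!is.null(loci)) Z <- Z[, loci, drop = FALSE]
  Z
}

#' Simulate founder genomes with drift-generated linkage disequilibrium
#'
#' Founders are drawn as offspring of a historical random-mating population
#' of constant size `ne` evolved for `n_hist_generations` generations by the
#' meiosis operator, starting from linkage equilibrium with allele
#' frequencies uniform on \[0.05, 0.95\]. Drift and linkage build up LD that
#' decays with map distance. Loci whose final minor-allele frequency falls
#' below 0.01 are resampled in the final generation at a fresh uniform
#' frequency (such loci carry no LD and are flagged in the `resampled`
#' attribute so QTL selection can avoid them).
#'
#' @param map A `gs_map`.
#' @param n_founders Number of founder individuals to draw.
#' @param ne Historical effective population size (>= 2).
#' @param n_hist_generations Number of historical generations.
#' @param seed Optional integer seed.
#' @return A `gs_geno` with founder haplotypes (ids `1:n_founders`).
#' @export
simulate_founder_genomes <- function(map, n_founders, ne = 100,
                                     n_hist_generations = 100, seed = NULL) {
  stopifnot(nrow(map) >= 1, ne >= 2, n_founders >= 1,
            n_hist_generations >= 0)
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(map)
  p0 <- runif(m, 0.05, 0.95)
  draw_hap <- function(n) {
    matrix(as.integer(rbinom(n * m, 1L, rep(p0, each = n))), nrow = n)
  }
  hp <- draw_hap(ne)
  hm <- draw_hap(ne)
  pos <- map$position
  chrom <- as.integer(map$chromosome)
  cl <- chrom_lengths(map)
  gen_offspring <- function(hp, hm, n_off) {
    n_par <- nrow(hp)
    sires <- sample.int(n_par, n_off, replace = TRUE)
    dams <- sample.int(n_par, n_off, replace = TRUE)
    list(pat = cpp_drop_gametes(hp, hm, sires, pos, chrom, cl),
         mat = cpp_drop_gametes(hp, hm, dams, pos, chrom, cl))
  }
  if (n_hist_generations > 0) {
    for (g in seq_len(n_hist_generations)) {
      off <- gen_offspring(hp, hm, ne)
      hp <- off$pat
      hm <- off$mat
    }
  }
  fo <- gen_offspring(hp, hm, n_founders)
  hp <- fo$pat
  hm <- fo$mat

  # resample degenerate loci (MAF < 0.01) in the final generation
  resampled <- rep(FALSE, m)
  for (attempt in 1:20) {
    freq <- (colSums(hp) + colSums(hm)) / (2 * n_founders)
    bad <- which(pmin(freq, 1 - freq) < 0.01)
    if (!length(bad)) break
    if (attempt == 20L) {
      stop("degenerate locus: could not attain polymorphism at ",
           length(bad), " loci after bounded resampling", call. = FALSE)
    }
    for (j in bad) {
      pj <- runif(1, 0.05, 0.95)
      hp[, j] <- rbinom(n_founders, 1L, pj)
      hm[, j] <- rbinom(n_founders, 1L, pj)
    }
    resampled[bad] <- TRUE
  }
  g <- new_geno(map, hp, hm, seq_len(n_founders))
  attr(g, "resampled") <- resampled
  g
}

#' Gene-drop founder genomes through a pedigree
#'
#' Every non-founder receives a paternal gamete sampled by [meiose()] from
#' its sire and a maternal gamete from its dam, so parental origin labels
#' are preserved through the drop.
#'
#' @param pedigree A `gs_pedigree` (parents before offspring).
#' @param founders A `gs_geno` holding one haplotype pair per pedigree
#'   founder, in founder order.
#' @return A `gs_geno` over all pedigree members.
#' @export
drop_pedigree <- function(pedigree, founders) {
  n <- nrow(pedigree)
  is_founder <- is.na(pedigree$sire) & is.na(pedigree$dam)
  if (sum(is_founder) != nrow(founders$hap_pat)) {
    stop("founder genotype rows must match pedigree founders", call. = FALSE)
  }
  m <- nrow(founders$map)
  idx <- seq_len(n)
  hp <- matrix(0L, n, m)
  hm <- matrix(0L, n, m)
  hp[is_founder, ] <- founders$hap_pat
  hm[is_founder, ] <- founders$hap_mat
  depth <- integer(n)
  pos_of <- stats::setNames(idx, pedigree$id)
  for (i in idx[!is_founder]) {
    s <- pos_of[[as.character(pedigree$sire[i])]]
    d <- pos_of[[as.character(pedigree$dam[i])]]
    if (s >= i || d >= i) stop("offspring precedes parent", call. = FALSE)
    depth[i] <- 1L + max(depth[s], depth[d])
  }
  pos <- founders$map$position
  chrom <- as.integer(founders$map$chromosome)
  cl <- chrom_lengths(founders$map)
  for (lev in sort(unique(depth[depth > 0L]))) {
    at <- idx[depth == lev]
    s_rows <- pos_of[as.character(pedigree$sire[at])]
    d_rows <- pos_of[as.character(pedigree$dam[at])]
    hp[at, ] <- cpp_drop_gametes(hp, hm, as.integer(s_rows), pos, chrom, cl)
    hm[at, ] <- cpp_drop_gametes(hp, hm, as.integer(d_rows), pos, chrom, cl)
  }
  new_geno(founders$map, hp, hm, pedigree$id)
}

hw_probs <- function(p) c((1 - p)^2, 2 * p * (1 - p), p^2)

epi_marginals <- function(tab, p1, p2) {
  P1 <- hw_probs(p1)
  P2 <- hw_probs(p2)
  m1 <- as.vector(tab %*% P2)
  m2 <- as.vector(t(tab) %*% P1)
  list(m1 = m1 - sum(P1 * m1), m2 = m2 - sum(P2 * m2))
}

#' Assign an 8-QTL trait architecture to simulated founders
#'
#' Places QTL with the layout 1/2/2/1/2 over five chromosomes: one large
#' additive QTL on chromosome 1, two linked additive QTL (< 0.2 Morgan
#' apart) on each of chromosomes 2 and 3, one paternally expressed imprinted
#' QTL on chromosome 4, and an epistatic pair on chromosome 5 whose 3x3
#' genotype-value table is a centred dosage product, giving (near) zero
#' marginal additive effects. Raw per-QTL variance shares are gamma draws
#' with the chromosome-1 QTL forced largest by rejection; all effects are
#' then rescaled by one common factor so the realised true-breeding-value
#' variance among the founders equals `sigma2_g`.
#'
#' The stored `sigma2_e` is the full non-additive-plus-environmental budget
#' `sigma2_g (1 - h2) / h2`; the environmental noise actually drawn by
#' [simulate_phenotypes()] is `sigma2_e` minus the realised non-additive
#' genetic variance (`var_nonadd`), so the narrow-sense heritability
#' Var(TBV)/Var(y) hits the `h2` target.
#'
#' @param map A `gs_map` over at least 5 chromosomes.
#' @param founder_data Founder `gs_geno` from [simulate_founder_genomes()].
#' @param h2 Narrow-sense heritability target in (0, 1).
#' @param sigma2_g Additive-genetic variance target.
#' @param seed Optional integer seed.
#' @return A `gs_architecture` list: `qtls` data frame (`snp_id`,
#'   `chromosome`, `position`, `kind`, `locus`, `effect`, `freq`),
#'   `epi_table`, `sigma2_g`, `h2`, `sigma2_e`, `var_nonadd`, `sigma2_resid`.
#' @export
assign_architecture <- function(map, founder_data, h2 = 0.3, sigma2_g = 1,
                                seed = NULL) {
  stopifnot(h2 > 0, h2 < 1, sigma2_g > 0)
  if (!is.null(seed)) set.seed(seed)
  Z <- dosages(founder_data)
  freq <- colMeans(Z) / 2
  maf <- pmin(freq, 1 - freq)
  resampled <- attr(founder_data, "resampled")
  if (is.null(resampled)) resampled <- rep(FALSE, nrow(map))
  eligible <- maf >= 0.05 & !resampled
  pick <- function(cc, n_pick, max_dist = NULL, min_dist = NULL) {
    cand <- which(eligible & map$chromosome == cc)
    if (length(cand) < n_pick) cand <- which(maf >= 0.05 & map$chromosome == cc)
    if (length(cand) < n_pick) {
      stop("architecture error: fewer than ", n_pick,
           " segregating loci on chromosome ", cc, call. = FALSE)
    }
    if (n_pick == 1L) return(sample(cand, 1L))
    for (try in 1:100) {
      a <- sample(cand, 1L)
      d <- abs(map$position[cand] - map$position[a])
      ok <- cand[cand != a &
                   (is.null(max_dist) | d <= (max_dist %||% Inf)) &
                   (is.null(min_dist) | d >= (min_dist %||% 0))]
      if (length(ok)) return(c(a, sample(ok, 1L)))
    }
    stop("architecture error: no locus pair satisfying the distance ",
         "constraint on chromosome ", cc, call. = FALSE)
  }
  loci <- c(pick(1, 1),
            pick(2, 2, max_dist = 0.2),
            pick(3, 2, max_dist = 0.2),
            pick(4, 1),
            pick(5, 2, min_dist = min(0.3, max(chrom_lengths(map)) / 3)))
  kind <- c("additive", "additive", "additive", "additive", "additive",
            "imprinted", "epistatic", "epistatic")
  p <- freq[loci]

  # raw variance shares; chromosome-1 QTL forced largest by rejection
  for (try in 1:50) {
    v <- c(rgamma(1, 6), rgamma(4, 2), rgamma(1, 2))
    if (v[1] > max(v[-1])) break
    if (try == 50L) v[1] <- 1.05 * max(v[-1])
  }
  v_epi <- rgamma(1, 2)
  sgn <- sample(c(-1, 1), 7, replace = TRUE)
  eff <- numeric(8)
  eff[1:5] <- sgn[1:5] * sqrt(v[1:5] / (2 * p[1:5] * (1 - p[1:5])))
  eff[6] <- sgn[6] * sqrt(v[6] / (p[6] * (1 - p[6])))
  c_epi <- sgn[7] * sqrt(v_epi / (4 * prod(p[7:8] * (1 - p[7:8]))))
  eff[7:8] <- c_epi

  build <- function(eff, c_epi) {
    tab <- outer(0:2 - 2 * p[7], 0:2 - 2 * p[8]) * c_epi
    arch <- list(
      qtls = data.frame(
        snp_id = map$snp_id[loci], chromosome = map$chromosome[loci],
        position = map$position[loci], kind = kind, locus = loci,
        effect = eff, freq = unname(p)),
      epi_table = tab, sigma2_g = sigma2_g, h2 = h2,
      sigma2_e = sigma2_g * (1 - h2) / h2)
    class(arch) <- "gs_architecture"
    arch
  }
  arch <- build(eff, c_epi)
  tbv_raw <- compute_tbv(founder_data, arch)
  v_raw <- stats::var(tbv_raw)
  if (v_raw <= 0) stop("architecture error: zero raw genetic variance",
                       call. = FALSE)
  s <- sqrt(sigma2_g / v_raw)
  arch <- build(eff * s, c_epi * s)
  g_full <- genotypic_value(founder_data, arch)
  tbv_f <- compute_tbv(founder_data, arch)
  arch$var_nonadd <- stats::var(g_full - tbv_f)
  arch$sigma2_resid <- arch$sigma2_e - arch$var_nonadd
  if (arch$sigma2_resid <= 0) {
    stop("architecture error: non-additive variance exceeds the ",
         "environmental budget", call. = FALSE)
  }
  arch
}

`%||%` <- function(a, b) if (is.null(a)) b else a

qtl_columns <- function(geno, arch) {
  loc <- match(arch$qtls$snp_id, geno$map$snp_id)
  if (anyNA(loc)) {
    stop("QTL loci ", paste(arch$qtls$snp_id[is.na(loc)], collapse = ", "),
         " absent from genotypes", call. = FALSE)
  }
  loc
}

#' True breeding values under an architecture
#'
#' The TBV is the sum of average-effect contributions: additive QTL
#' contribute `a (dosage - 2p)`; the imprinted (paternally expressed) QTL
#' contributes `a (paternal allele - p)`, read from the parental-origin
#' labels; each member of the epistatic pair contributes its centred
#' marginal mean computed from the 3x3 genotype-value table under
#' Hardy-Weinberg founder frequencies.
#'
#' @param geno A `gs_geno` containing the QTL loci (haplotypes required
#'   when an imprinted QTL is present).
#' @param arch A `gs_architecture`.
#' @return Named numeric vector of TBV per individual.
#' @export
compute_tbv <- function(geno, arch) {
  loc <- qtl_columns(geno, arch)
  Z <- dosages(geno)
  tbv <- numeric(nrow(Z))
  q <- arch$qtls
  for (k in which(q$kind == "additive")) {
    tbv <- tbv + q$effect[k] * (Z[, loc[k]] - 2 * q$freq[k])
  }
  for (k in which(q$kind == "imprinted")) {
    if (is.null(geno$hap_pat)) {
      stop("parental-origin labels required for the imprinted QTL ",
           "but genotypes carry dosages only", call. = FALSE)
    }
    tbv <- tbv + q$effect[k] * (geno$hap_pat[, loc[k]] - q$freq[k])
  }
  ke <- which(q$kind == "epistatic")
  if (length(ke) == 2L) {
    mg <- epi_marginals(arch$epi_table, q$freq[ke[1]], q$freq[ke[2]])
    tbv <- tbv + mg$m1[Z[, loc[ke[1]]] + 1] + mg$m2[Z[, loc[ke[2]]] + 1]
  }
  names(tbv) <- rownames(Z)
  tbv
}

# full genotypic value: non-marginalised imprinting and epistasis terms
genotypic_value <- function(geno, arch) {
  loc <- qtl_columns(geno, arch)
  Z <- dosages(geno)
  g <- numeric(nrow(Z))
  q <- arch$qtls
  for (k in which(q$kind == "additive")) {
    g <- g + q$effect[k] * (Z[, loc[k]] - 2 * q$freq[k])
  }
  for (k in which(q$kind == "imprinted")) {
    g <- g + q$effect[k] * (geno$hap_pat[, loc[k]] - q$freq[k])
  }
  ke <- which(q$kind == "epistatic")
  if (length(ke) == 2L) {
    P <- outer(hw_probs(q$freq[ke[1]]), hw_probs(q$freq[ke[2]]))
    tab_c <- arch$epi_table - sum(P * arch$epi_table)
    g <- g + tab_c[cbind(Z[, loc[ke[1]]] + 1, Z[, loc[ke[2]]] + 1)]
  }
  names(g) <- rownames(Z)
  g
}

#' Simulate phenotypes from genotypic values
#'
#' Phenotypes are `y = mu + genotypic value + e` with
#' `e ~ N(0, sigma2_e - var_nonadd)`; the genotypic value keeps the full
#' (non-marginalised) imprinting and epistatic terms. Within each full-sib
#' family the first `ceiling(fraction * k)` offspring (by id) are
#' phenotyped; founders never are.
#'
#' @param tbv True breeding values (from [compute_tbv()]).
#' @param arch A `gs_architecture`.
#' @param pedigree A `gs_pedigree`.
#' @param geno A `gs_geno` over the pedigree.
#' @param phenotyped_fraction Fraction of each full-sib family phenotyped,
#'   in (0, 1].
#' @param mu Trait mean.
#' @param seed Optional integer seed.
#' @return A `data.frame` of class `gs_pheno` with columns `id`, `y` (`NA`
#'   when unphenotyped), `tbv`, `phenotyped`.
#' @export
simulate_phenotypes <- function(tbv, arch, pedigree, geno,
                                phenotyped_fraction = 2 / 3, mu = 0,
                                seed = NULL) {
  if (!is.numeric(phenotyped_fraction) || phenotyped_fraction <= 0 ||
      phenotyped_fraction > 1) {
    stop("phenotyped_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  g_full <- genotypic_value(geno, arch)
  n <- nrow(pedigree)
  y <- mu + g_full + rnorm(n, 0, sqrt(arch$sigma2_resid))
  phen <- rep(FALSE, n)
  off <- which(pedigree$generation != "founder")
  fam <- interaction(pedigree$sire[off], pedigree$dam[off], drop = TRUE)
  for (f in split(off, fam)) {
    k <- ceiling(phenotyped_fraction * length(f))
    phen[f[order(pedigree$id[f])][seq_len(k)]] <- TRUE
  }
  out <- data.frame(id = pedigree$id, y = ifelse(phen, y, NA_real_),
                    tbv = as.numeric(tbv), phenotyped = phen)
  class(out) <- c("gs_pheno", "data.frame")
  out
}

#' Simulate a complete genomic-selection benchmark dataset
#'
#' End-to-end generator reproducing the statistical structure of the
#' 15th QTLMAS workshop data: a 20 x 10 x 15 pedigree (3220 individuals,
#' 20 half-sib and 200 full-sib families), about 10000 SNP on five 1-Morgan
#' chromosomes, 8 QTL (layout 1/2/2/1/2 with imprinting on chromosome 4 and
#' epistasis on chromosome 5), trait heritability 0.3, and two thirds
#' (2000) of the offspring phenotyped. QTL are placed at map loci but
#' excluded from the marker panel (`Z`), i.e. they are unobserved.
#'
#' A master seed drives per-stage child seeds (recorded in `meta`), so the
#' same seed reproduces the dataset bit-identically.
#'
#' @param n_sires,dams_per_sire,offspring_per_dam Pedigree structure.
#' @param snps_per_chrom,n_chrom,chrom_length Genome map.
#' @param h2 Narrow-sense heritability target.
#' @param sigma2_g Additive-genetic variance.
#' @param ne,n_hist_generations Historical population for founder LD.
#' @param phenotyped_fraction Phenotyped fraction per full-sib family.
#' @param seed Master seed.
#' @return A `gs_sim` list: `pedigree`, `map` (all loci), `geno`, `arch`,
#'   `pheno`, `markers` (marker snp ids), `Z` (marker dosage matrix over
#'   all individuals), `meta`.
#' @examples
#' sim <- sim_gsdata(n_sires = 2, dams_per_sire = 2, offspring_per_dam = 6,
#'                   snps_per_chrom = 60, ne = 20, n_hist_generations = 20,
#'                   seed = 1)
#' dim(sim$Z)
#' @export
sim_gsdata <- function(n_sires = 20, dams_per_sire = 10,
                       offspring_per_dam = 15, snps_per_chrom = 2000,
                       n_chrom = 5, chrom_length = 1, h2 = 0.3,
                       sigma2_g = 1, ne = 100, n_hist_generations = 100,
                       phenotyped_fraction = 2 / 3, seed = 1) {
  set.seed(seed)
  child <- sample.int(.Machine$integer.max - 1L, 4L)
  map <- make_map(snps_per_chrom, n_chrom, chrom_length)
  ped <- build_pedigree(n_sires, dams_per_sire, offspring_per_dam)
  n_founders <- sum(ped$generation == "founder")
  founders <- simulate_founder_genomes(map, n_founders, ne = ne,
                                       n_hist_generations = n_hist_generations,
                                       seed = child[1])
  arch <- assign_architecture(map, founders, h2 = h2, sigma2_g = sigma2_g,
                              seed = child[2])
  set.seed(child[3])
  geno <- drop_pedigree(ped, founders)
  tbv <- compute_tbv(geno, arch)
  pheno <- simulate_phenotypes(tbv, arch, ped, geno,
                               phenotyped_fraction = phenotyped_fraction,
                               seed = child[4])
  marker_idx <- setdiff(seq_len(nrow(map)), arch$qtls$locus)
  Z <- dosages(geno)[, marker_idx, drop = FALSE]
  sim <- list(pedigree = ped, map = map, geno = geno, arch = arch,
              pheno = pheno, markers = map$snp_id[marker_idx], Z = Z,
              meta = list(seed = seed, child_seeds = child,
                          params = list(n_sires = n_sires,
                                        dams_per_sire = dams_per_sire,
                                        offspring_per_dam = offspring_per_dam,
                                        snps_per_chrom = snps_per_chrom,
                                        n_chrom = n_chrom,
                                        chrom_length = chrom_length, h2 = h2,
                                        sigma2_g = sigma2_g, ne = ne,
                                        n_hist_generations = n_hist_generations,
                                        phenotyped_fraction =
                                          phenotyped_fraction)))
  class(sim) <- "gs_sim"
  sim
}

#' @export
print.gs_sim <- function(x, ...) {
  p <- x$meta$params
  cat("Simulated genomic-selection dataset\n")
  cat(sprintf("  individuals: %d (%d founders, %d offspring)\n",
              nrow(x$pedigree),
              sum(x$pedigree$generation == "founder"),
              sum(x$pedigree$generation != "founder")))
  cat(sprintf("  markers: %d on %d chromosomes (+%d hidden QTL)\n",
              ncol(x$Z), p$n_chrom, nrow(x$arch$qtls)))
  cat(sprintf("  phenotyped: %d; h2 target %.2f\n",
              sum(x$pheno$phenotyped), p$h2))
  invisible(x)
}
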