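# shared fixtures; heavyweight simulations are cached so several test files
# can reuse one realisation

.gs_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .gs_cache)) {
    assign(key, force(expr), envir = .gs_cache)
  }
  get(key, envir = .gs_cache)
}

# benchmark-scale dataset, slimmed to what the tests consume
benchmark_sim <- function(seed) {
  cached(paste0("bench", seed), {
    sim <- sim_gsdata(seed = seed)
    marker_map <- sim$map[match(sim$markers, sim$map$snp_id), ]
    list(pedigree = sim$pedigree, pheno = sim$pheno, arch = sim$arch,
         Z = sim$Z, marker_map = marker_map)
  })
}

# small pedigreed dataset for unit tests
small_sim <- function(seed = 3) {
  cached(paste0("small", seed),
         sim_gsdata(n_sires = 4, dams_per_sire = 3, offspring_per_dam = 8,
                    snps_per_chrom = 80, ne = 30, n_hist_generations = 25,
                    seed = seed))
}

# hand-built architecture over an explicit map
make_test_arch <- function(map, loci, kinds, effects, freqs,
                           epi_table = NULL, sigma2_g = 1, h2 = 0.3,
                           sigma2_resid = NULL) {
  arch <- list(
    qtls = data.frame(snp_id = map$snp_id[loci],
                      chromosome = map$chromosome[loci],
                      position = map$position[loci], kind = kinds,
                      locus = loci, effect = effects, freq = freqs),
    epi_table = epi_table, sigma2_g = sigma2_g, h2 = h2,
    sigma2_e = sigma2_g * (1 - h2) / h2, var_nonadd = 0,
    sigma2_resid = sigma2_resid %||% (sigma2_g * (1 - h2) / h2))
  class(arch) <- "gs_architecture"
  arch
}

# genotype object from explicit haplotype matrices
make_test_geno <- function(map, hap_pat, hap_mat) {
  g <- list(map = map, hap_pat = hap_pat, hap_mat = hap_mat,
            ids = seq_len(nrow(hap_pat)), dosage = NULL)
  class(g) <- "gs_geno"
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
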