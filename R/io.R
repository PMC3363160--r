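#' @name gs_io
#' @title Plain-text readers and writers for the pipeline formats
#'
#' @description All stage inputs and outputs are tab-separated text (plus
#' JSON for the architecture and run manifest): pedigree TSV (`id`, `sire`,
#' `dam`, `generation`; 0 = unknown parent), map TSV (`snp_id`, `chrom`,
#' `pos_morgan`), dosage TSV (header of snp ids, first column `id`),
#' phenotype TSV (`id`, `y` with `NA` for missing, `tbv`), GEBV TSV (`id`,
#' `gebv`, `pev`), SNP-effect TSV (`snp_id`, `beta`, `inclusion_prob`).
NULL

#' @rdname gs_io
#' @param pedigree,path Object to write and file path.
#' @export
write_pedigree <- function(pedigree, path) {
  out <- data.frame(id = pedigree$id,
                    sire = ifelse(is.na(pedigree$sire), 0L, pedigree$sire),
                    dam = ifelse(is.na(pedigree$dam), 0L, pedigree$dam),
                    generation = pedigree$generation)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname gs_io
#' @export
read_pedigree <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  ped <- data.frame(id = as.integer(d$id),
                    sire = ifelse(d$sire == 0, NA_integer_,
                                  as.integer(d$sire)),
                    dam = ifelse(d$dam == 0, NA_integer_, as.integer(d$dam)),
                    generation = d$generation)
  class(ped) <- c("gs_pedigree", "data.frame")
  ped
}

#' @rdname gs_io
#' @param map A `gs_map`.
#' @export
write_map <- function(map, path) {
  utils::write.table(
    data.frame(snp_id = map$snp_id, chrom = map$chromosome,
               pos_morgan = map$position),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname gs_io
#' @export
read_map <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  map <- data.frame(snp_id = d$snp_id, chromosome = as.integer(d$chrom),
                    position = as.numeric(d$pos_morgan))
  class(map) <- c("gs_map", "data.frame")
  map
}

#' @rdname gs_io
#' @param Z Dosage matrix (individuals x SNP).
#' @export
write_dosages <- function(Z, path) {
  d <- data.frame(id = rownames(Z) %||% seq_len(nrow(Z)), Z,
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype dosage table
#'
#' Validates every cell against the dosage alphabet 0/1/2/NA and reports
#' the first malformed cell by row and column; optionally attaches a map
#' and checks it against the matrix columns.
#'
#' @param path Dosage TSV as written by [write_dosages()].
#' @param map_path Optional companion map TSV.
#' @return A `gs_geno` carrying the dosage matrix (no haplotypes); the
#'   per-SNP missingness is in the `missingness` attribute.
#' @export
read_genotypes <- function(path, map_path = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (!ncol(d) >= 2) stop("parse error: no SNP columns in ", path,
                          call. = FALSE)
  ids <- d[[1]]
  M <- as.matrix(d[, -1, drop = FALSE])
  ok <- M %in% c("0", "1", "2", "NA", "") | is.na(M)
  if (!all(ok)) {
    bad <- which(!matrix(ok, nrow(M)), arr.ind = TRUE)[1, ]
    stop(sprintf("parse error: malformed dosage %s at row %d, column %d of %s",
                 M[bad[1], bad[2]], bad[1], bad[2] + 1L, path),
         call. = FALSE)
  }
  Z <- matrix(suppressWarnings(as.numeric(M)), nrow(M),
              dimnames = list(ids, colnames(M)))
  map <- NULL
  if (!is.null(map_path)) {
    map <- read_map(map_path)
    if (!identical(map$snp_id, colnames(Z))) {
      keep <- match(colnames(Z), map$snp_id)
      if (anyNA(keep)) stop("alignment error: map and dosage columns differ",
                            call. = FALSE)
      map <- map[keep, ]
    }
  }
  g <- new_geno(map, NULL, NULL, ids, dosage = Z)
  attr(g, "missingness") <- colMeans(is.na(Z))
  g
}

#' @rdname gs_io
#' @param pheno A `gs_pheno`.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno[, c("id", "y", "tbv")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname gs_io
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  d$phenotyped <- !is.na(d$y)
  class(d) <- c("gs_pheno", "data.frame")
  d
}

#' @rdname gs_io
#' @param arch A `gs_architecture`.
#' @export
write_architecture <- function(arch, path) {
  jsonlite::write_json(
    list(qtls = arch$qtls, epi_table = arch$epi_table,
         sigma2_g = arch$sigma2_g, h2 = arch$h2, sigma2_e = arch$sigma2_e,
         var_nonadd = arch$var_nonadd, sigma2_resid = arch$sigma2_resid),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname gs_io
#' @export
read_architecture <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  arch <- list(qtls = as.data.frame(j$qtls), epi_table = j$epi_table,
               sigma2_g = j$sigma2_g, h2 = j$h2, sigma2_e = j$sigma2_e,
               var_nonadd = j$var_nonadd, sigma2_resid = j$sigma2_resid)
  class(arch) <- "gs_architecture"
  arch
}

#' @rdname gs_io
#' @param fit A `gsfit` (or list with `gebv`/`pev`).
#' @export
write_gebv <- function(fit, path) {
  utils::write.table(
    data.frame(id = names(fit$gebv), gebv = as.numeric(fit$gebv),
               pev = as.numeric(fit$pev)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname gs_io
#' @export
read_gebv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  list(gebv = stats::setNames(d$gebv, d$id),
       pev = stats::setNames(d$pev, d$id))
}

#' @rdname gs_io
#' @param sim A `gs_sim` dataset.
#' @param dir Output directory (created if needed).
#' @export
write_gsdata <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pedigree(sim$pedigree, file.path(dir, "pedigree.tsv"))
  write_map(sim$map[match(sim$markers, sim$map$snp_id), ],
            file.path(dir, "map.tsv"))
  write_dosages(sim$Z, file.path(dir, "dosages.tsv"))
  write_phenotypes(sim$pheno, file.path(dir, "phenotypes.tsv"))
  write_architecture(sim$arch, file.path(dir, "architecture.json"))
  jsonlite::write_json(sim$meta, file.path(dir, "simulation_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# ---------------------------------------------------------------------------
# configuration and pipeline orchestration
# ---------------------------------------------------------------------------

default_config <- function() {
  list(
    simulate = list(n_sires = 20, dams_per_sire = 10, offspring_per_dam = 15,
                    snps_per_chrom = 2000, n_chrom = 5, chrom_length = 1,
                    h2 = 0.3, sigma2_g = 1, ne = 100,
                    n_hist_generations = 100, phenotyped_fraction = 2 / 3),
    methods = c("pblup", "gblup", "lasso", "bayesa", "bbn", "bbt"),
    prior = list(df = "estimate", pi = "estimate", lambda = "estimate"),
    chain = list(burn_in = 10000, n_samples = 10000, thin = 20,
                 df_multiplier = 5),
    evaluate = list(set = "offspring"),
    scan = list(enabled = TRUE),
    master_seed = 1,
    log_level = "info")
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key", if (length(unknown) > 1) "s", ": ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  }
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      merge_config(defaults[[k]], user[[k]], paste0(path, k, "."))
    } else {
      user[[k]]
    }
  }
  defaults
}

#' Build a validated pipeline configuration
#'
#' Defaults reproduce the benchmark-scale experiment (20 x 10 x 15
#' pedigree, 2000 SNP per chromosome, h2 = 0.3, burn-in 10000, 10000
#' retained samples thinned by 20, schedule multiplier 5 when `df` is
#' estimated). Unknown keys are rejected.
#'
#' @param config Named list of overrides, or a path to a YAML file.
#' @param ... Further overrides (take precedence over `config`), e.g.
#'   `simulate = list(n_sires = 2)`.
#' @return Validated configuration list of class `gs_config`.
#' @export
gs_config <- function(config = NULL, ...) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  cfg <- merge_config(cfg, list(...))
  bad <- setdiff(cfg$methods,
                 c("pblup", "gblup", "lasso", "bayesa", "bbn", "bbt"))
  if (length(bad)) stop("unknown method: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  class(cfg) <- c("gs_config", "list")
  cfg
}

log_stage <- function(level, ...) {
  message(sprintf("[gsbench %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(...)))
}

write_manifest <- function(manifest, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full benchmark pipeline
#'
#' Executes simulate -> pedigree BLUP -> GBLUP -> whole-genome regression
#' (each requested method) -> evaluation -> GRAMMAR scan, writing every
#' stage product as plain text under `out_dir` together with a JSON run
#' manifest (config snapshot, per-stage seeds and timings, file checksums)
#' sufficient to re-run any stage bit-identically. A stage failure aborts
#' downstream stages; the manifest records the partial completion.
#'
#' @param config A `gs_config` (or overrides list / YAML path accepted by
#'   [gs_config()]).
#' @param out_dir Output directory.
#' @param seed Master seed overriding `config$master_seed`.
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(config = gs_config(), out_dir, seed = NULL) {
  if (!inherits(config, "gs_config")) config <- gs_config(config)
  if (!is.null(seed)) config$master_seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("gsbench")),
                   config = unclass(config), stages = list(), files = list())
  mpath <- file.path(out_dir, "manifest.json")
  set.seed(config$master_seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 16L)
  tic <- function() proc.time()[["elapsed"]]
  finish_stage <- function(name, t0, files, seed = NULL) {
    manifest$stages[[name]] <<- list(
      seconds = round(tic() - t0, 2), seed = seed, files = files)
    for (f in files) manifest$files[[basename(f)]] <<-
        unname(tools::md5sum(f))
    write_manifest(manifest, mpath)
  }

  # simulate
  t0 <- tic()
  log_stage("info", "simulate: %d individuals",
            with(config$simulate,
                 n_sires * (1 + dams_per_sire * (1 + offspring_per_dam))))
  sim <- do.call(sim_gsdata, c(config$simulate, seed = stage_seeds[1]))
  write_gsdata(sim, out_dir)
  finish_stage("simulate", t0, file.path(out_dir,
    c("pedigree.tsv", "map.tsv", "dosages.tsv", "phenotypes.tsv",
      "architecture.json", "simulation_meta.json")),
    seed = stage_seeds[1])

  fits <- list()
  chain_cfg <- do.call(chain_config, config$chain)
  k <- 2L
  for (m in config$methods) {
    t0 <- tic()
    log_stage("info", "fit %s", m)
    fits[[m]] <- if (m == "pblup") {
      gsfit(sim$pheno, method = "pblup", pedigree = sim$pedigree)
    } else if (m == "gblup") {
      gsfit(sim$pheno, method = "gblup", geno = sim$Z)
    } else {
      gsfit(sim$pheno, method = m, geno = sim$Z,
            prior = do.call(prior_spec, c(list(method = m), config$prior)),
            chain = chain_cfg, seed = stage_seeds[k])
    }
    fp <- file.path(out_dir, paste0("gebv_", m, ".tsv"))
    write_gebv(fits[[m]], fp)
    files <- fp
    if (!is.null(fits[[m]]$beta)) {
      ep <- file.path(out_dir, paste0("effects_", m, ".tsv"))
      utils::write.table(fits[[m]]$beta, ep, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      hp <- file.path(out_dir, paste0("hyper_", m, ".json"))
      jsonlite::write_json(
        list(posterior_means = fits[[m]]$hyper,
             schedule = fits[[m]]$schedule,
             trace = fits[[m]]$trace),
        hp, auto_unbox = TRUE, digits = NA, dataframe = "columns")
      files <- c(files, ep, hp)
    }
    finish_stage(m, t0, files,
                 seed = if (!(m %in% c("pblup", "gblup"))) stage_seeds[k])
    k <- k + 1L
  }

  # evaluate
  t0 <- tic()
  log_stage("info", "evaluate")
  off_ids <- as.character(
    sim$pedigree$id[sim$pedigree$generation != "founder"])
  tbv <- stats::setNames(sim$pheno$tbv, as.character(sim$pheno$id))
  rep_fits <- fits[setdiff(names(fits), "pblup")]
  report <- evaluate_methods(
    if (length(rep_fits)) rep_fits else fits, tbv,
    blup_fit = fits[["pblup"]], ids = off_ids)
  rp <- file.path(out_dir, "report.json")
  jsonlite::write_json(
    list(table = report$table, r_blup = report$r_blup,
         concordance = if (!is.null(report$concordance))
           list(methods = report$concordance$methods,
                correlations = report$concordance$correlations,
                min = report$concordance$min,
                max = report$concordance$max)),
    rp, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  finish_stage("evaluate", t0, rp)

  if (isTRUE(config$scan$enabled)) {
    t0 <- tic()
    log_stage("info", "scan")
    sc <- grammar_scan(sim$pheno, sim$Z, pedigree = sim$pedigree,
                       map = sim$map)
    sp <- file.path(out_dir, "scan.tsv")
    utils::write.table(as.data.frame(sc), sp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    finish_stage("scan", t0, sp)
  }
  invisible(manifest)
}
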