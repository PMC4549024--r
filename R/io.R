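## File formats: genotype TSV and PLINK-.raw-style dosage files,
## pedigree CSV, phenotype TSV, truth TSV, YAML configs, JSON fit
## summaries and TSV chain stores.  Dosages are written 0/1/2 for allele
## M; locus ids are 1-based in files.  Missing genotypes are not
## supported and raise an error naming the offending cell.

#' Write / read a genotype dosage matrix as TSV
#'
#' Rows are individuals (first column `id`), remaining columns one per
#' marker (`m1`, `m2`, ...), entries 0/1/2.
#'
#' @param dosages integer matrix of dosages.
#' @param path file path.
#' @param ids individual identifiers (default 1..n).
#' @return `readGenotypesTSV()` returns the integer dosage matrix with
#'   ids as rownames.
#' @export
writeGenotypesTSV <- function(dosages, path, ids = seq_len(nrow(dosages))) {
  df <- data.frame(id = ids, dosages)
  names(df) <- c("id", paste0("m", seq_len(ncol(dosages))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGenotypesTSV
#' @export
readGenotypesTSV <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  checkDosageCells(mat, path)
  storage.mode(mat) <- "integer"
  rownames(mat) <- df$id
  colnames(mat) <- names(df)[-1]
  mat
}

checkDosageCells <- function(mat, path) {
  bad <- which(!(mat %in% c(0, 1, 2)) | is.na(mat))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(mat)) + 1
    j <- ((bad[1] - 1) %/% nrow(mat)) + 1
    stop("malformed dosage in ", path, " at row ", i, ", marker column ",
         j, " (missing genotypes are not supported)")
  }
}

#' Write / read PLINK .raw-style dosage files
#'
#' Columns `FID IID PAT MAT SEX PHENOTYPE` followed by one allele-count
#' column per marker (`m<j>_M`, counting allele M).
#'
#' @param dosages integer dosage matrix.
#' @param path file path.
#' @param fid,iid,pat,mat,sex,phenotype metadata columns (sensible
#'   defaults).
#' @return `readRaw()` returns the integer dosage matrix.
#' @export
writeRaw <- function(dosages, path, fid = seq_len(nrow(dosages)),
                     iid = seq_len(nrow(dosages)), pat = 0, mat = 0,
                     sex = 0, phenotype = -9) {
  df <- data.frame(FID = fid, IID = iid, PAT = pat, MAT = mat, SEX = sex,
                   PHENOTYPE = phenotype, dosages)
  names(df) <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE",
                 paste0("m", seq_len(ncol(dosages)), "_M"))
  write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRaw
#' @export
readRaw <- function(path) {
  df <- read.table(path, header = TRUE, sep = " ",
                   stringsAsFactors = FALSE, na.strings = c("NA", "-9."))
  mat <- as.matrix(df[, -(1:6), drop = FALSE])
  checkDosageCells(mat, path)
  storage.mode(mat) <- "integer"
  rownames(mat) <- df$IID
  mat
}

#' Write / read a pedigree CSV
#'
#' Columns `id, sire, dam, family`; parent id 0 denotes an unknown
#' (founder) parent.
#'
#' @param ped data.frame with `id`, `sire`, `dam` (and optionally
#'   `family`).
#' @param path file path.
#' @param family family labels (recycled into the file when `ped` lacks
#'   them).
#' @return `readPedigreeCSV()` returns the pedigree data.frame.
#' @export
writePedigreeCSV <- function(ped, path, family = NULL) {
  if (is.null(ped$family))
    ped$family <- if (is.null(family)) 0L else family
  write.table(ped, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePedigreeCSV
#' @export
readPedigreeCSV <- function(path) {
  ped <- read.table(path, header = TRUE, sep = ",",
                    stringsAsFactors = FALSE)
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(ped)))
    stop("pedigree file must have columns id, sire, dam")
  ped
}

#' Write / read phenotypes as TSV
#' @param y phenotype vector.
#' @param path file path.
#' @param ids individual ids.
#' @return `readPhenotypesTSV()` returns a data.frame `id`, `y`.
#' @export
writePhenotypesTSV <- function(y, path, ids = seq_along(y)) {
  write.table(data.frame(id = ids, y = y), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePhenotypesTSV
#' @export
readPhenotypesTSV <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write the truth file of a replicate
#'
#' True breeding values, dominance deviations and genotypic values per
#' individual, as TSV.
#'
#' @param truth list with `u_a`, `u_d`, `g` (from [trueValues()]).
#' @param path file path.
#' @param ids individual ids.
#' @export
writeTruthTSV <- function(truth, path, ids = seq_along(truth$u_a)) {
  write.table(data.frame(id = ids, u_a = truth$u_a, u_d = truth$u_d,
                         g = truth$g),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Save / load an MCMC chain as TSV
#'
#' The scalar samples, posterior-mean effects and the configuration are
#' written to `<path>.samples.tsv`, `<path>.effects.tsv` and
#' `<path>.config.yaml`.
#'
#' @param chain an [MCMCChain-class].
#' @param path base path (without extension).
#' @return `readChainTSV()` reconstructs the [MCMCChain-class] (without
#'   retained per-iteration effects).
#' @export
writeChainTSV <- function(chain, path) {
  write.table(chain@samples, paste0(path, ".samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  eff <- data.frame(post_mean_ma = chain@post_mean_ma,
                    post_mean_md = chain@post_mean_md,
                    post_mean_tau2a = chain@post_mean_tau2a,
                    post_mean_tau2d = chain@post_mean_tau2d)
  write.table(eff, paste0(path, ".effects.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- chain@config
  yaml::write_yaml(list(method = cfg@method, df1 = cfg@df1,
                        df2 = cfg@df2, prior_family = cfg@prior_family,
                        n_iter = cfg@n_iter, burn_in = cfg@burn_in,
                        thin = cfg@thin, h2a0 = cfg@h2a0,
                        h2d0 = cfg@h2d0),
                   paste0(path, ".config.yaml"))
  invisible(path)
}

#' @rdname writeChainTSV
#' @export
readChainTSV <- function(path) {
  samples <- read.table(paste0(path, ".samples.tsv"), header = TRUE,
                        sep = "\t")
  eff <- read.table(paste0(path, ".effects.tsv"), header = TRUE,
                    sep = "\t")
  cfg <- yaml::read_yaml(paste0(path, ".config.yaml"))
  config <- modelConfig(cfg$method, n_iter = cfg$n_iter,
                        burn_in = cfg$burn_in, thin = cfg$thin,
                        h2a0 = cfg$h2a0, h2d0 = cfg$h2d0)
  new("MCMCChain", samples = samples, post_mean_ma = eff$post_mean_ma,
      post_mean_md = eff$post_mean_md,
      post_mean_tau2a = eff$post_mean_tau2a,
      post_mean_tau2d = eff$post_mean_tau2d, config = config,
      effects = matrix(numeric(0), 0, 0))
}

#' Write a fit summary as JSON
#'
#' @param fit a fit list from `fitMethodOnReplicate()` /
#'   [posteriorSummary()]-style summaries.
#' @param path file path.
#' @param seed,config_hash provenance fields stored alongside.
#' @export
writeFitJSON <- function(fit, path, seed = NA, config_hash = NA) {
  keep <- fit[intersect(names(fit),
                        c("method", "class", "h2a", "h2d", "vd_va"))]
  keep$seed <- seed
  keep$config_hash <- config_hash
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Hash of a configuration list (provenance stamping)
#'
#' Deterministic short hash of the YAML serialization; artifacts record
#' it together with the generating seed.
#'
#' @param config a list.
#' @return character(1) hash.
#' @export
configHash <- function(config) {
  txt <- yaml::as.yaml(config)
  ## polynomial rolling hash over the serialized text (28-bit state so
  ## every intermediate stays exactly representable in a double)
  h <- 17
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 268435456
  sprintf("%07x", h)
}
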