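#' Read a sample-by-feature matrix from a tab-separated file
#'
#' Expected layout: header row of feature ids, first column of sample ids,
#' numeric cells. Dosage matrices are additionally validated to lie in
#' [0, 2]; a violation is reported with its sample and feature. Missing
#' values are allowed in expression matrices (they are dropped per-test
#' downstream, with a logged count) but not in dosage matrices.
#'
#' @param path file path.
#' @param kind \code{"dosage"} or \code{"expression"}.
#' @return numeric matrix with sample rownames and feature colnames.
#' @export
readMatrix <- function(path, kind = c("dosage", "expression")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("matrix file needs a sample-id column plus features: ", path)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1L], is.numeric, logical(1)))[1L]
    stop("non-numeric cells in column '", colnames(df)[bad + 1L], "' of ", path)
  }
  rownames(m) <- ids
  if (kind == "dosage") {
    if (anyNA(m)) stop("missing values are not allowed in a dosage matrix: ", path)
    off <- which(m < 0 | m > 2, arr.ind = TRUE)
    if (nrow(off))
      stop(sprintf("dosage out of [0, 2] at sample '%s', SNP '%s' in %s",
                   rownames(m)[off[1L, 1L]], colnames(m)[off[1L, 2L]], path))
  }
  m
}

#' @rdname readMatrix
#' @export
readDosageMatrix <- function(path) readMatrix(path, "dosage")

#' @rdname readMatrix
#' @export
readExpressionMatrix <- function(path) readMatrix(path, "expression")

#' Read genotype dosages from a VCF file
#'
#' Convenience converter: takes the DS FORMAT field when present, otherwise
#' counts alternate alleles in GT. Requires the \pkg{vcfR} package.
#'
#' @param path VCF path (may be bgzipped).
#' @return samples x SNPs numeric dosage matrix.
#' @export
readVcfDosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fmt <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":")))
  if ("DS" %in% fmt) {
    d <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    d <- apply(gt, c(1, 2), function(x) {
      if (is.na(x)) return(NA_real_)
      sum(as.integer(strsplit(x, "[/|]")[[1]]) > 0)
    })
  }
  ids <- vcfR::getID(v)
  ids[is.na(ids)] <- paste0("var", which(is.na(ids)))
  rownames(d) <- ids
  t(d)
}

#' Assemble a ScreeningDataset from matrix and annotation files
#'
#' @param genoPath tab-separated dosage matrix (samples x SNPs, integer
#'   0/1/2).
#' @param exprPath tab-separated expression matrix (samples x probes).
#' @param annotPath tab-separated annotation with columns \code{id},
#'   \code{chrom}, \code{pos}, \code{is_tf} covering every SNP and probe
#'   (\code{is_tf} is ignored for SNPs).
#' @return A [ScreeningDataset-class] with an empty truth ledger.
#' @export
screeningDatasetFromFiles <- function(genoPath, exprPath, annotPath) {
  geno <- readDosageMatrix(genoPath)
  expr <- readExpressionMatrix(exprPath)
  if (!identical(rownames(geno), rownames(expr)))
    stop("sample ids of the dosage and expression matrices differ")
  ann <- utils::read.table(annotPath, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos", "is_tf")
  if (!all(need %in% colnames(ann)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  missing <- setdiff(c(colnames(geno), colnames(expr)), ann$id)
  if (length(missing))
    stop("annotation missing for: ", paste(utils::head(missing, 5), collapse = ", "))
  ann <- ann[match(c(colnames(geno), colnames(expr)), ann$id), ]
  mk <- function(ids) {
    a <- ann[match(ids, ann$id), ]
    gr <- GRanges(a$chrom, IRanges(a$pos, width = 1L))
    names(gr) <- ids
    gr
  }
  if (any(geno != round(geno)))
    stop("screening requires hard-called integer dosages (0/1/2)")
  snpSE <- SummarizedExperiment(assays = list(dosage = t(geno)),
                                rowRanges = mk(colnames(geno)))
  exprSE <- SummarizedExperiment(assays = list(expr = t(expr)),
                                 rowRanges = mk(colnames(expr)))
  rowData(exprSE)$is_tf <- as.logical(ann$is_tf[match(colnames(expr), ann$id)])
  new("ScreeningDataset", snpData = snpSE, exprData = exprSE,
      truth = DataFrame(type = character(), snp = character(),
                        probe = character(), partner = character(),
                        tau = numeric()))
}

#' Write a ScreeningDataset to tab-separated files
#'
#' Writes \code{geno.tsv}, \code{expr.tsv} and \code{annot.tsv} in the
#' layout read back by [screeningDatasetFromFiles()].
#'
#' @param ds a [ScreeningDataset-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
writeScreeningDataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("geno.tsv", "expr.tsv", "annot.tsv"))
  .writeMat <- function(m, path) {
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  .writeMat(genotypeMatrix(ds), paths[1])
  .writeMat(expressionMatrix(ds), paths[2])
  sc <- .featureCoords(snpRanges(ds))
  pc <- .featureCoords(probeRanges(ds))
  ann <- rbind(data.frame(sc, is_tf = FALSE),
               data.frame(pc, is_tf = unname(isTF(ds))))
  utils::write.table(ann, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Write a tidy results table
#'
#' Tab-separated with header; p-value-like columns (names starting with
#' "p" or ending in "P") are rendered in scientific notation with 6
#' significant digits, other numeric columns with up to 8. Row order is
#' preserved, so identical inputs give byte-identical files.
#'
#' @param table non-empty data.frame.
#' @param path output path.
#' @export
writeResults <- function(table, path) {
  if (!is.data.frame(table) || !nrow(table))
    stop("refusing to write an empty results table")
  out <- table
  for (cn in colnames(out)) {
    if (!is.numeric(out[[cn]])) next
    if (grepl("^p[A-Z]?|P$", cn) || cn == "p") {
      out[[cn]] <- formatC(out[[cn]], format = "e", digits = 6)
    } else {
      out[[cn]] <- formatC(out[[cn]], format = "g", digits = 8)
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a run configuration for [dispatch()]
#'
#' @param command one of \code{"simulate"}, \code{"test"}, \code{"sweep"},
#'   \code{"grid"}, \code{"screen"}.
#' @param params named list of command-specific parameters.
#' @param seed root seed.
#' @param outDir output directory.
#' @param verbose logical.
#' @return list of class \code{"RunConfig"}.
#' @export
runConfig <- function(command, params = list(), seed = 1L,
                      outDir = ".", verbose = TRUE) {
  command <- match.arg(command, c("simulate", "test", "sweep", "grid", "screen"))
  structure(list(command = command, params = params, seed = as.integer(seed),
                 outDir = outDir, verbose = isTRUE(verbose)),
            class = "RunConfig")
}

.log <- function(cfg, ...) {
  if (cfg$verbose) message(...)
}

.writeManifest <- function(cfg, outputs) {
  manifest <- list(command = cfg$command, params = cfg$params,
                   seed = cfg$seed,
                   version = as.character(utils::packageVersion("interscreen")),
                   outputs = outputs)
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Execute a configured run
#'
#' Routes a [runConfig()] to the simulator, the single-test runner, the
#' interaction-sweep or robustness-grid drivers, or the trio-screening
#' pipeline; writes tab-separated outputs plus a \code{manifest.json}
#' (resolved configuration, seed, package version) into the output
#' directory. Logs go to stderr so stdout stays pipe-safe.
#'
#' @param cfg a \code{RunConfig}.
#' @return Invisibly, 0 on success (errors propagate as conditions).
#' @export
dispatch <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  p <- cfg$params
  outputs <- character()
  get <- function(name, default = NULL) {
    if (!is.null(p[[name]])) p[[name]] else default
  }
  if (cfg$command == "simulate") {
    cfgS <- scenarioConfig(
      n = get("n", 1000L), caf = get("caf", 0.3),
      tauG = get("tauG", 0), tauE = get("tauE", 0),
      tauZ = get("tauZ", 0), tauGE = get("tauGE", 0),
      distE = get("distE", "normal"), distZ = get("distZ", "normal"),
      distEps = get("distEps", "normal"), meanE = get("meanE", 0),
      seed = cfg$seed)
    coh <- buildCohort(cfgS)
    f <- file.path(cfg$outDir, "cohort.tsv")
    utils::write.table(as.data.frame(coh), f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs <- f
    .log(cfg, "wrote cohort of ", cfgS@n, " individuals")
  } else if (cfg$command == "test") {
    for (req in c("y", "g", "z"))
      if (is.null(p[[req]])) stop("missing required input file: --", req)
    readVec <- function(f) {
      if (!file.exists(f)) stop("file not found: ", f)
      scan(f, quiet = TRUE)
    }
    strategy <- get("strategy", "std")
    if (!strategy %in% .ALL_STRATEGIES)
      stop("unknown strategy '", strategy, "'; valid: ",
           paste(.ALL_STRATEGIES, collapse = ", "))
    res <- testInteraction(readVec(p$y), readVec(p$g), readVec(p$z),
                           strategy = strategy, rkt = isTRUE(p$rkt))
    f <- file.path(cfg$outDir, "interaction_test.tsv")
    writeResults(data.frame(strategy = res@strategy, rkt = res@rkt,
                            beta = res@beta, se = res@se, wald = res@wald,
                            p = res@p), f)
    outputs <- f
  } else if (cfg$command == "sweep") {
    sw <- runTauSweep(tauGrid = get("tauGrid", seq(0, 0.3, by = 0.05)),
                      regime = get("regime", "none"),
                      n = get("n", 400L), reps = get("reps", 10000L),
                      caf = get("caf", 0.3), seed = cfg$seed)
    f1 <- file.path(cfg$outDir, "sweep_summary.tsv")
    f2 <- file.path(cfg$outDir, "sweep_profiles.tsv")
    writeResults(sw$summary, f1)
    writeResults(sw$profiles, f2)
    outputs <- c(f1, f2)
  } else if (cfg$command == "grid") {
    gc <- gridConfig(nList = get("nList", c(100L, 500L, 1000L, 5000L)),
                     cafList = get("cafList", c(0.05, 0.3, 0.5)),
                     distRegimes = get("distRegimes", c("normal", "right_skew")),
                     mainEffectRegimes = get("mainEffectRegimes",
                                             c("E_only", "Z_only", "both", "neither")),
                     replicatesPerCell = get("reps", 20000L),
                     seed = cfg$seed)
    res <- runGrid(gc, strategies = get("strategies", c("std", "hc0", "hc3")))
    f <- file.path(cfg$outDir, "grid_summary.tsv")
    writeResults(res, f)
    outputs <- f
  } else { # screen
    for (req in c("geno", "expr", "annot"))
      if (is.null(p[[req]])) stop("missing required input file: --", req)
    ds <- screeningDatasetFromFiles(p$geno, p$expr, p$annot)
    hits <- selectCisEqtls(ds, window = get("window", 250000),
                           qMax = get("qmax", 0.01))
    if (!nrow(hits)) stop("no cis-eQTL hit; nothing to screen")
    trios <- buildTrios(ds, hits, tfPMax = get("tfP", 0.05),
                        exclusion = get("excl", 1e7))
    if (!nrow(trios)) stop("all candidate trios were filtered out")
    res <- screenTrios(ds, trios, sig = get("sig", 1e-8))
    f1 <- file.path(cfg$outDir, "trios.tsv")
    f2 <- file.path(cfg$outDir, "stratified_lambda.tsv")
    writeResults(res, f1)
    writeResults(stratifiedLambda(res), f2)
    outputs <- c(f1, f2)
    .log(cfg, "screened ", nrow(res), " trios")
  }
  .writeManifest(cfg, outputs)
  invisible(0L)
}
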