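# Staged pipeline: sample -> encode -> train -> evaluate, each stage writing
# its artifact plus a provenance record (config echo, hash, seeds, package
# version) into the run directory, so a run is reproducible from its config
# alone.  runAll() chains all stages.

#' Read a pipeline run configuration
#'
#' JSON file with keys: \code{ontology} (path to an OBO file) or
#' \code{fixture} (a [fixtureSpec()]-style object to generate one),
#' \code{root} (optional root term), \code{n_classes},
#' \code{members_per_class}, \code{seed}, \code{fractions} (train/val/test
#' triple), \code{encoder} (\code{"fingerprint"}, \code{"token_character"}
#' or \code{"token_atom"}), \code{model} (either
#' \code{{"type": "classical", "algorithm": ..., "kernel": ...}} or
#' \code{{"type": "lstm", ...networkConfig keys...}}) and
#' \code{output_dir}.
#'
#' @param path JSON config path.
#' @return Config list (validated).
#' @export
readRunConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg Config list (as from JSON).
#' @export
validateRunConfig <- function(cfg) {
  if (is.null(cfg$ontology) && is.null(cfg$fixture))
    stop("config needs either 'ontology' (OBO path) or 'fixture'",
         call. = FALSE)
  for (key in c("n_classes", "members_per_class", "output_dir"))
    if (is.null(cfg[[key]]))
      stop("config key missing: ", key, call. = FALSE)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$fractions)) cfg$fractions <- c(0.7, 0.1, 0.2)
  if (is.null(cfg$encoder)) cfg$encoder <- "fingerprint"
  cfg$encoder <- match.arg(cfg$encoder,
                           c("fingerprint", "token_character", "token_atom"))
  if (is.null(cfg$model))
    cfg$model <- list(type = "classical", algorithm = "LR")
  if (!cfg$model$type %in% c("classical", "lstm"))
    stop("model type must be 'classical' or 'lstm'", call. = FALSE)
  if (cfg$model$type == "lstm" && cfg$encoder == "fingerprint")
    stop("the lstm model consumes token sequences; ",
         "set encoder to token_character or token_atom", call. = FALSE)
  cfg
}

.configHash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

.writeProvenance <- function(cfg, dir, stage) {
  rec <- list(stage = stage, config = cfg, config_hash = .configHash(cfg),
              seed = cfg$seed,
              package_version = as.character(utils::packageVersion("chemont")),
              r_version = R.version.string)
  jsonlite::write_json(rec, file.path(dir, paste0("provenance_", stage,
                                                  ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.stageFile <- function(cfg, name) file.path(cfg$output_dir, name)

.needUpstream <- function(cfg, file, stage) {
  p <- .stageFile(cfg, file)
  if (!file.exists(p))
    stop("missing artifact '", file, "': run stage '", stage,
         "' first", call. = FALSE)
  p
}

.loadConfigGraph <- function(cfg) {
  if (!is.null(cfg$ontology)) {
    loadOntology(cfg$ontology, root = cfg$root)
  } else {
    fx <- cfg$fixture
    makeToyOntology(fixtureSpec(
      nClasses = fx$n_classes, membersPerClass = fx$members_per_class,
      hierarchyDepth = if (is.null(fx$hierarchy_depth)) 3L
                       else fx$hierarchy_depth,
      overlapFraction = if (is.null(fx$overlap_fraction)) 0
                        else fx$overlap_fraction,
      seed = if (is.null(fx$seed)) cfg$seed else fx$seed))
  }
}

#' Pipeline stages
#'
#' \code{runSample()} samples a balanced N-by-M dataset from the configured
#' ontology (or generated fixture), splits it and writes
#' \code{dataset.tsv}.  \code{runEncode()} encodes the dataset's SMILES
#' (fingerprints or token sequences) into \code{encoded.rds}.
#' \code{runTrain()} fits the configured model on the training partition and
#' writes \code{model.rds} (plus \code{history.csv} for the network).
#' \code{runEvaluate()} scores the test partition and writes
#' \code{report.json}/\code{report.tsv} (plus \code{predictions.tsv}).
#' \code{runAll()} chains the four stages.  Every stage writes a provenance
#' record; rerunning with the same config reproduces identical dataset files
#' and identical classical-model predictions.
#'
#' @param cfg Config list from [readRunConfig()], or a path to a JSON
#'   config.
#' @return The written artifact path(s), invisibly; \code{runEvaluate()}
#'   returns the evaluation report list.
#' @export
runSample <- function(cfg) {
  cfg <- .asConfig(cfg)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  graph <- .loadConfigGraph(cfg)
  ds <- selectBalanced(graph, cfg$n_classes, cfg$members_per_class,
                       seed = cfg$seed)
  sp <- splitDataset(ds, fractions = as.numeric(cfg$fractions),
                     seed = cfg$seed)
  writeDatasetTsv(sp, .stageFile(cfg, "dataset.tsv"))
  writeOntology(graph, .stageFile(cfg, "ontology.obo"))
  .writeProvenance(cfg, cfg$output_dir, "sample")
  invisible(.stageFile(cfg, "dataset.tsv"))
}

.asConfig <- function(cfg) {
  if (is.character(cfg)) readRunConfig(cfg) else validateRunConfig(cfg)
}

#' @rdname runSample
#' @export
runEncode <- function(cfg) {
  cfg <- .asConfig(cfg)
  tab <- readDatasetTsv(.needUpstream(cfg, "dataset.tsv", "sample"))
  enc <- if (cfg$encoder == "fingerprint") {
    list(encoder = "fingerprint",
         x = smilesFingerprint(stats::setNames(tab$smiles, tab$member_id)))
  } else {
    mode <- if (cfg$encoder == "token_atom") "atom" else "character"
    seqs <- tokenizeSmiles(tab$smiles, mode = mode)
    vocab <- buildVocabulary(seqs[tab$split == "train"])
    x <- encodeSequences(seqs, vocab, padTo = max(lengths(seqs)))
    rownames(x) <- tab$member_id
    list(encoder = cfg$encoder, x = x, vocabulary = vocab)
  }
  saveRDS(enc, .stageFile(cfg, "encoded.rds"))
  .writeProvenance(cfg, cfg$output_dir, "encode")
  invisible(.stageFile(cfg, "encoded.rds"))
}

#' @rdname runSample
#' @export
runTrain <- function(cfg) {
  cfg <- .asConfig(cfg)
  tab <- readDatasetTsv(.needUpstream(cfg, "dataset.tsv", "sample"))
  enc <- readRDS(.needUpstream(cfg, "encoded.rds", "encode"))
  isTrain <- tab$split == "train"
  if (cfg$model$type == "classical") {
    spec <- classifierSpec(cfg$model$algorithm,
                           kernel = cfg$model$kernel,
                           hyperparameters = as.list(
                             cfg$model$hyperparameters),
                           seed = cfg$seed)
    model <- trainClassical(spec, enc$x[isTrain, , drop = FALSE],
                            tab$class_id[isTrain])
  } else {
    nc <- cfg$model
    nc$type <- NULL
    nc <- utils::modifyList(networkConfig(seed = cfg$seed), nc)
    labels <- sort(unique(tab$class_id))
    isVal <- tab$split == "validation"
    y <- labelMatrix(tab$class_id, labels)
    model <- trainLstm(
      nc, enc$x[isTrain, , drop = FALSE], y[isTrain, , drop = FALSE],
      xVal = if (any(isVal)) enc$x[isVal, , drop = FALSE],
      yVal = if (any(isVal)) y[isVal, , drop = FALSE],
      classLabels = labels, vocabulary = enc$vocabulary)
    writeHistoryCsv(model, .stageFile(cfg, "history.csv"))
  }
  saveModel(model, .stageFile(cfg, "model.rds"))
  .writeProvenance(cfg, cfg$output_dir, "train")
  invisible(.stageFile(cfg, "model.rds"))
}

#' @rdname runSample
#' @export
runEvaluate <- function(cfg) {
  cfg <- .asConfig(cfg)
  tab <- readDatasetTsv(.needUpstream(cfg, "dataset.tsv", "sample"))
  enc <- readRDS(.needUpstream(cfg, "encoded.rds", "encode"))
  model <- loadModel(.needUpstream(cfg, "model.rds", "train"))
  graph <- loadOntology(.needUpstream(cfg, "ontology.obo", "sample"))
  isTest <- tab$split == "test"
  testIds <- tab$member_id[isTest]
  truth <- stats::setNames(tab$class_id[isTest], testIds)

  if (is(model, "ClassicalModel")) {
    pred <- stats::setNames(
      predict(model, enc$x[isTest, , drop = FALSE]), testIds)
    report <- scoreSingleLabel(pred, truth,
                               classes = sort(unique(tab$class_id)))
    predTsv <- data.frame(member_id = testIds,
                          predicted_class_id = unname(pred))
    predSets <- lapply(pred, identity)
  } else {
    scores <- predictScores(model, enc$x[isTest, , drop = FALSE])
    predSets <- stats::setNames(
      predictClasses(scores, threshold = model@config$threshold), testIds)
    ml <- scoreMultiLabel(predSets, lapply(truth, identity),
                          classes = model@classLabels)
    report <- ml
    predTsv <- data.frame(
      member_id = testIds,
      predicted_class_id = vapply(predSets, paste, character(1),
                                  collapse = ";"))
  }
  plr <- pathLengthReport(
    graph,
    asserted = lapply(truth, identity),
    predicted = lapply(predSets, function(p) condenseClasses(graph, p)))

  utils::write.table(predTsv, .stageFile(cfg, "predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  classReport <- if (is.data.frame(report)) report else report$classReport
  out <- list(classReport = classReport,
              macro = as.list(attr(classReport, "macro")),
              pathLength = list(mean = plr$mean,
                                noPathCount = plr$noPathCount),
              abstentions = if (!is.data.frame(report)) report$abstentions)
  jsonlite::write_json(out, .stageFile(cfg, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  utils::write.table(classReport, .stageFile(cfg, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .writeProvenance(cfg, cfg$output_dir, "evaluate")
  invisible(out)
}

#' @rdname runSample
#' @export
runAll <- function(cfg) {
  cfg <- .asConfig(cfg)
  runSample(cfg)
  runEncode(cfg)
  runTrain(cfg)
  runEvaluate(cfg)
}
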