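# End-to-end audit pipeline: clean -> featurize -> train/bounds -> report.
#
# One top-level seed; every stage draws from a named substream so stages are
# independently reproducible. Every artifact written in a run is listed in
# the manifest with a content digest, and rerunning an identical config
# reproduces digest-identical outputs.

#' Default pipeline configuration
#'
#' @param ... overrides merged over the defaults (top level only).
#' @return a config list; see the fields in the source for the schema.
#' @export
audit_config <- function(...) {
  cfg <- list(
    seed = 1L,
    outdir = "audit_run",
    input = list(type = "planted", n_reactions = 400L, label_noise = 0.2,
                 duplicate_rate = 0.05, missing_rate = 0.05, path = NULL),
    target = "yield",
    threshold = NULL,            # NULL -> median of the cleaned set
    features = "descriptors",    # descriptors | fp | cld | mixed
    folds = 4L,
    model = "rf",                # rf | ert | lasso
    num_trees = 200L,
    fp_length = 256L,
    cld = list(n_pairs = 150L, K = 15L, min_size = 3L, timeout_s = 2),
    curves = list(num_features = NULL, sizes = NULL),
    bounds = list(k = 1L)
  )
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  cfg
}

validate_config <- function(cfg) {
  if (!is.list(cfg)) stop("config must be a list")
  if (is.null(cfg$seed) || !is.numeric(cfg$seed)) stop("config: seed must be numeric")
  if (is.null(cfg$folds) || cfg$folds < 2L) stop("config: folds must be >= 2")
  if (!cfg$target %in% c("yield", "time")) stop("config: target must be yield or time")
  if (!cfg$features %in% c("descriptors", "fp", "cld", "mixed")) {
    stop("config: features must be one of descriptors, fp, cld, mixed")
  }
  if (!cfg$model %in% c("rf", "ert", "lasso")) stop("config: unknown model")
  if (!cfg$input$type %in% c("planted", "file")) stop("config: input type")
  invisible(cfg)
}

log_stage <- function(stage, ...) {
  message(jsonlite::toJSON(c(list(stage = stage, time = format(Sys.time())),
                             list(...)), auto_unbox = TRUE))
}

#' Assemble a feature matrix for a labeled reaction set
#'
#' @param labeled a `labeled_reactions` object.
#' @param families `"descriptors"`, `"fp"`, `"cld"` or `"mixed"`
#'   (descriptors + fingerprints + CLDs).
#' @param fp_length folded fingerprint length.
#' @param cld_vocab a [mine_clds()] vocabulary (required for cld/mixed).
#' @param cld_K number of CLD bits.
#' @param ... passed to [reaction_features()].
#' @return numeric matrix with family-tagged columns.
#' @export
assemble_features <- function(labeled, families = "descriptors",
                              fp_length = 256L, cld_vocab = NULL,
                              cld_K = NULL, ...) {
  stopifnot(inherits(labeled, "labeled_reactions"))
  recs <- labeled$records
  blocks <- list()
  fam <- character(0)
  if (families %in% c("descriptors", "mixed")) {
    B <- reaction_features(recs, ...)
    fam <- c(fam, attr(B, "family")); blocks <- c(blocks, list(B))
  }
  if (families %in% c("fp", "mixed")) {
    B <- fingerprint_matrix(recs, L = fp_length)
    fam <- c(fam, attr(B, "family")); blocks <- c(blocks, list(B))
  }
  if (families %in% c("cld", "mixed")) {
    if (is.null(cld_vocab)) stop("cld features need a vocabulary")
    B <- cld_matrix(recs, cld_vocab, K = cld_K %||% nrow(cld_vocab))
    fam <- c(fam, attr(B, "family")); blocks <- c(blocks, list(B))
  }
  X <- do.call(cbind, blocks)
  rownames(X) <- recs$reaction_id
  attr(X, "family") <- fam
  X
}

file_digest <- function(path) digest::digest(file = path, algo = "xxhash64")

#' Run the full predictability audit pipeline
#'
#' Stages: obtain records (generate planted data or read a file), clean and
#' deduplicate, label, featurize, cross-validate the classifier, estimate
#' the Bayes-error bound band, optionally trace error curves, and write
#' curve CSVs plus a JSON run manifest with content digests.
#'
#' @param config a config list from [audit_config()] or a YAML file path.
#' @return the run manifest (invisibly written to `<outdir>/manifest.json`).
#' @export
run_pipeline <- function(config = audit_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(utils::modifyList(audit_config(), config))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  inputs <- list()

  # -- records ---------------------------------------------------------
  if (cfg$input$type == "planted") {
    log_stage("simulate", n = cfg$input$n_reactions)
    gen <- planted_reactions(
      n_reactions = cfg$input$n_reactions,
      label_noise = cfg$input$label_noise %||% 0.2,
      duplicate_rate = cfg$input$duplicate_rate %||% 0,
      missing_rate = cfg$input$missing_rate %||% 0,
      target = cfg$target,
      seed = derive_seed(cfg$seed, "simulate")
    )
    raw <- gen$records
  } else {
    log_stage("read", path = cfg$input$path)
    raw <- read_reactions(cfg$input$path)
    inputs[[cfg$input$path]] <- file_digest(cfg$input$path)
  }

  # -- clean -----------------------------------------------------------
  log_stage("clean", n_raw = nrow(raw))
  cl <- clean_reactions(raw)
  recs <- deduplicate_reactions(cl$records, target = cfg$target)
  rej_path <- file.path(cfg$outdir, "rejects.jsonl")
  write_rejects_jsonl(cl$rejects, rej_path)
  artifacts[["rejects.jsonl"]] <- file_digest(rej_path)

  thr <- cfg$threshold %||% median_threshold(recs, cfg$target)
  labeled <- label_reactions(recs, label_spec(cfg$target, threshold = thr))
  lab_path <- file.path(cfg$outdir, "labeled.csv")
  write_labeled_csv(labeled, lab_path)
  artifacts[["labeled.csv"]] <- file_digest(lab_path)

  # -- featurize -------------------------------------------------------
  log_stage("featurize", families = cfg$features)
  vocab <- NULL
  if (cfg$features %in% c("cld", "mixed")) {
    smis <- unique(unlist(lapply(labeled$records$rsmi, function(r) {
      s <- split_rsmi(r); c(s$reactants, s$products)
    }), use.names = FALSE))
    vocab <- mine_clds(smis, n_pairs = cfg$cld$n_pairs,
                       seed = derive_seed(cfg$seed, "cld"),
                       min_size = cfg$cld$min_size,
                       timeout_s = cfg$cld$timeout_s)
    voc_path <- file.path(cfg$outdir, "cld_vocabulary.tsv")
    write_cld_vocabulary(vocab, voc_path)
    artifacts[["cld_vocabulary.tsv"]] <- file_digest(voc_path)
  }
  X <- assemble_features(labeled, cfg$features, fp_length = cfg$fp_length,
                         cld_vocab = vocab,
                         cld_K = min(cfg$cld$K, if (is.null(vocab)) Inf else nrow(vocab)))
  y <- labeled$labels

  # -- train + bounds --------------------------------------------------
  log_stage("train", model = cfg$model, n = nrow(X), p = ncol(X))
  spec <- switch(cfg$model,
                 rf = rf_spec(num_trees = cfg$num_trees),
                 ert = ert_spec(num_trees = cfg$num_trees),
                 lasso = lasso_spec())
  cv <- cv_train_eval(X, y, spec, folds = cfg$folds,
                      seed = derive_seed(cfg$seed, "cv"))
  bde <- bound_estimate(X, y, k = cfg$bounds$k,
                        seed = derive_seed(cfg$seed, "bounds"))

  write_curve <- function(curve, name) {
    p <- file.path(cfg$outdir, name)
    utils::write.csv(as.data.frame(curve), p, row.names = FALSE)
    artifacts[[name]] <<- file_digest(p)
    p
  }
  results <- list(
    cv_mean_error = cv$mean_error, cv_std_error = cv$std_error,
    bayes_lower = bde$lower, bayes_upper = bde$upper, r_nn = bde$r_nn,
    threshold = thr, n_labeled = nrow(X), n_rejected = nrow(cl$rejects)
  )

  if (!is.null(cfg$curves$num_features)) {
    kg <- cfg$curves$num_features[cfg$curves$num_features <= ncol(X)]
    crv <- error_vs_num_features(X, y, kg, spec, folds = cfg$folds,
                                 seed = derive_seed(cfg$seed, "kcurve"))
    write_curve(crv, "error_vs_num_features.csv")
  }
  if (!is.null(cfg$curves$sizes)) {
    sg <- cfg$curves$sizes[cfg$curves$sizes <= nrow(X)]
    crv <- error_vs_dataset_size(X, y, sg, spec, folds = cfg$folds,
                                 seed = derive_seed(cfg$seed, "ncurve"))
    write_curve(crv, "error_vs_dataset_size.csv")
    bcrv <- bound_curve(X, y, sg, k = cfg$bounds$k,
                        seed = derive_seed(cfg$seed, "bband"))
    write_curve(bcrv, "bound_curve.csv")
  }

  # -- manifest --------------------------------------------------------
  manifest <- list(config = cfg, results = results,
                   inputs = inputs, artifacts = artifacts,
                   seeds = list(
                     simulate = derive_seed(cfg$seed, "simulate"),
                     cld = derive_seed(cfg$seed, "cld"),
                     cv = derive_seed(cfg$seed, "cv"),
                     bounds = derive_seed(cfg$seed, "bounds")
                   ))
  man_path <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  log_stage("report", outdir = cfg$outdir,
            cv_mean_error = cv$mean_error, bayes_lower = bde$lower)
  invisible(manifest)
}
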