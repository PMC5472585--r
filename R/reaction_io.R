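# Reaction record ingestion, validation, deduplication and binary labeling.
#
# Literature reaction sets arrive as reaction SMILES (`reactants>agents>products`)
# with per-record yield (%), time (h), solvent and temperature, and are messy:
# unparseable structures, missing outcomes, and the same transformation
# reported several times with conflicting numbers. The cleaning rules here
# follow the conventions used for curated high-throughput literature corpora:
# incomplete or unparseable entries are pruned (with a logged reason code);
# duplicate reactions keep the highest reported yield, or the shortest
# reported time, depending on the prediction target.

REJECT_REASONS <- c(
  malformed_rsmi     = "reaction SMILES does not have exactly two '>' separators or lacks a reactant/product",
  unparseable_smiles = "a component SMILES was rejected by the structure parser",
  missing_outcomes   = "both yield and time are missing",
  yield_out_of_range = "yield outside [0, 100]",
  nonpositive_time   = "time is not a positive number"
)

split_rsmi <- function(text) {
  parts <- strsplit(text, ">", fixed = TRUE)[[1]]
  # trailing empty field ("A>>" style) must survive the split
  n_sep <- lengths(regmatches(text, gregexpr(">", text, fixed = TRUE)))
  if (n_sep != 2L) return(NULL)
  parts <- c(parts, rep("", 3L - length(parts)))[1:3]
  split_side <- function(s) if (!nzchar(s)) character(0) else strsplit(s, ".", fixed = TRUE)[[1]]
  list(reactants = split_side(parts[1]), agents = split_side(parts[2]),
       products = split_side(parts[3]))
}

#' Parse a reaction SMILES into molecule lists
#'
#' Splits `reactants>agents>products`, parses every component molecule, and
#' returns the three molecule lists. The agent field may be empty; the
#' reactant and product fields must each contain at least one parseable
#' molecule.
#'
#' @param text one reaction SMILES string.
#' @return a list with `molgraph` lists `reactants`, `agents`, `products`.
#' @export
parse_rsmi <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  sides <- split_rsmi(text)
  if (is.null(sides)) stop("malformed reaction SMILES (need exactly two '>'): ", text)
  if (length(sides$reactants) == 0L || length(sides$products) == 0L) {
    stop("reaction SMILES needs at least one reactant and one product: ", text)
  }
  all_smi <- c(sides$reactants, sides$agents, sides$products)
  mols <- parse_molecules(all_smi)
  bad <- vapply(mols, is.null, FALSE)
  if (any(bad)) stop("unparseable component SMILES: ",
                     paste(all_smi[bad], collapse = ", "))
  nr <- length(sides$reactants); na <- length(sides$agents)
  list(reactants = mols[seq_len(nr)],
       agents = if (na > 0) mols[nr + seq_len(na)] else list(),
       products = mols[(nr + na + 1L):length(mols)])
}

#' Read a raw reaction table
#'
#' Accepts a CSV/TSV file with header columns
#' `rsmi,yield,time,solvent,temperature` (an optional `id` column is kept), or
#' a plain `.rsmi` file with one reaction SMILES per line and no outcome data.
#'
#' @param path file path.
#' @return a data.frame of raw records with columns `reaction_id`, `rsmi`,
#'   `yield_pct`, `time_h`, `solvent`, `temperature_c`.
#' @export
read_reactions <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "rsmi") {
    rsmi <- readLines(path, warn = FALSE)
    rsmi <- rsmi[nzchar(trimws(rsmi))]
    df <- data.frame(rsmi = trimws(rsmi), yield_pct = NA_real_, time_h = NA_real_,
                     solvent = NA_character_, temperature_c = NA_real_)
  } else {
    sep <- if (ext %in% c("tsv", "txt")) "\t" else ","
    raw <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, quote = "\"",
                             comment.char = "")
    need <- c("rsmi")
    if (!all(need %in% names(raw))) stop("missing required column(s): rsmi")
    df <- data.frame(
      rsmi = as.character(raw$rsmi),
      yield_pct = suppressWarnings(as.numeric(raw$yield %||% rep(NA, nrow(raw)))),
      time_h = suppressWarnings(as.numeric(raw$time %||% rep(NA, nrow(raw)))),
      solvent = as.character(raw$solvent %||% rep(NA_character_, nrow(raw))),
      temperature_c = suppressWarnings(as.numeric(raw$temperature %||% rep(NA, nrow(raw)))),
      stringsAsFactors = FALSE
    )
    if (!is.null(raw$id)) df$reaction_id <- as.character(raw$id)
  }
  if (is.null(df$reaction_id)) df$reaction_id <- sprintf("r%06d", seq_len(nrow(df)))
  df$solvent[!is.na(df$solvent) & !nzchar(trimws(df$solvent))] <- NA_character_
  df[c("reaction_id", "rsmi", "yield_pct", "time_h", "solvent", "temperature_c")]
}

# canonical, agent-insensitive dedup key: sorted canonical reactants ">" sorted
# canonical products
reaction_key <- function(rsmi) {
  sides <- lapply(rsmi, split_rsmi)
  all_smi <- unique(unlist(lapply(sides, function(s) {
    if (is.null(s)) NULL else c(s$reactants, s$products)
  }), use.names = FALSE))
  mols <- parse_molecules(all_smi %||% character(0))
  canmap <- stats::setNames(
    vapply(mols, function(g) if (is.null(g)) NA_character_ else g$cansmi, ""),
    all_smi)
  vapply(sides, function(s) {
    if (is.null(s)) return(NA_character_)
    r <- canmap[s$reactants]; p <- canmap[s$products]
    if (anyNA(r) || anyNA(p)) return(NA_character_)
    paste0(paste(sort(r), collapse = "."), ">", paste(sort(p), collapse = "."))
  }, "", USE.NAMES = FALSE)
}

#' Validate and prune raw reaction records
#'
#' Applies the pruning rules for literature reaction sets: records with a
#' malformed reaction SMILES, an unparseable component structure, both
#' outcomes missing, a yield outside \[0, 100\] or a non-positive time are
#' dropped, each with a machine-readable reason code. Surviving records gain
#' the canonical `dedup_key` used by [deduplicate_reactions()].
#'
#' @param records raw record data.frame from [read_reactions()].
#' @return a list with `records` (clean data.frame) and `rejects` (data.frame
#'   of `reaction_id`, `reason`).
#' @export
clean_reactions <- function(records) {
  stopifnot(is.data.frame(records), "rsmi" %in% names(records))
  n <- nrow(records)
  reason <- rep(NA_character_, n)

  sides <- lapply(records$rsmi, split_rsmi)
  malformed <- vapply(sides, function(s) {
    is.null(s) || length(s$reactants) == 0L || length(s$products) == 0L
  }, FALSE)
  reason[malformed] <- "malformed_rsmi"

  # batch-parse every component of structurally well-formed records
  comp <- unique(unlist(lapply(sides[!malformed], function(s) {
    c(s$reactants, s$agents, s$products)
  }), use.names = FALSE))
  mols <- parse_molecules(comp %||% character(0))
  ok_smi <- comp[!vapply(mols, is.null, FALSE)]
  unparse <- !malformed & vapply(sides, function(s) {
    if (is.null(s)) return(FALSE)
    !all(c(s$reactants, s$agents, s$products) %in% ok_smi)
  }, FALSE)
  reason[unparse & is.na(reason)] <- "unparseable_smiles"

  miss <- is.na(records$yield_pct) & is.na(records$time_h)
  reason[miss & is.na(reason)] <- "missing_outcomes"
  bad_y <- !is.na(records$yield_pct) & (records$yield_pct < 0 | records$yield_pct > 100)
  reason[bad_y & is.na(reason)] <- "yield_out_of_range"
  bad_t <- !is.na(records$time_h) & records$time_h <= 0
  reason[bad_t & is.na(reason)] <- "nonpositive_time"

  keep <- is.na(reason)
  clean <- records[keep, , drop = FALSE]
  clean$dedup_key <- reaction_key(clean$rsmi)
  rownames(clean) <- NULL
  list(records = clean,
       rejects = data.frame(reaction_id = records$reaction_id[!keep],
                            reason = reason[!keep], stringsAsFactors = FALSE))
}

#' Collapse duplicate reactions
#'
#' Two records are duplicates when they share the canonical (reactants,
#' products) pair, regardless of agents, solvent or temperature. For
#' `target = "yield"` the surviving record carries the highest reported yield
#' among its duplicates; for `target = "time"` the shortest reported time.
#' Output order is deterministic (sorted by dedup key).
#'
#' @param records clean record data.frame (from [clean_reactions()]); a
#'   `dedup_key` column is computed if absent.
#' @param target `"yield"` or `"time"`.
#' @return the deduplicated data.frame.
#' @export
deduplicate_reactions <- function(records, target = c("yield", "time")) {
  target <- match.arg(target)
  if (nrow(records) == 0L) return(records)
  if (is.null(records$dedup_key)) records$dedup_key <- reaction_key(records$rsmi)
  val <- if (target == "yield") records$yield_pct else records$time_h
  # pick per key: max yield / min time; NA values lose to any number;
  # remaining ties resolved by reaction_id for determinism
  score <- if (target == "yield") ifelse(is.na(val), -Inf, val) else ifelse(is.na(val), Inf, -val)
  ord <- order(records$dedup_key, -score, records$reaction_id)
  sorted <- records[ord, , drop = FALSE]
  keep <- !duplicated(sorted$dedup_key)
  out <- sorted[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Specify a binary outcome labeling rule
#'
#' The positive class is `value > threshold` (strict). For yield the default
#' threshold is 65 (a typical corpus median); for time it is 12 h (the
#' boundary between well-specified times and "left overnight" reporting), so
#' the positive class for time is the SLOW reactions.
#'
#' @param target `"yield"` or `"time"`.
#' @param threshold numeric cut in the target's units; defaults 65 / 12.
#' @param positive_class_name label for the positive class.
#' @return a `label_spec` object.
#' @export
label_spec <- function(target = c("yield", "time"), threshold = NULL,
                       positive_class_name = NULL) {
  target <- match.arg(target)
  threshold <- threshold %||% if (target == "yield") 65 else 12
  positive_class_name <- positive_class_name %||% if (target == "yield") "high_yield" else "slow"
  structure(list(target = target, threshold = threshold,
                 positive_class_name = positive_class_name),
            class = "label_spec")
}

#' @export
print.label_spec <- function(x, ...) {
  cat("<label_spec> ", x$target, " > ", x$threshold, " -> ",
      x$positive_class_name, " (ties to class 0)\n", sep = "")
  invisible(x)
}

#' Median-based threshold for a target
#'
#' Sample median of the observed target values; for even n the lower of the
#' two middle order statistics (so a median split puts the median record
#' itself in the low class under the strict `>` rule).
#'
#' @param records record data.frame.
#' @param target `"yield"` or `"time"`.
#' @return the threshold value.
#' @export
median_threshold <- function(records, target = c("yield", "time")) {
  target <- match.arg(target)
  v <- if (target == "yield") records$yield_pct else records$time_h
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("no observed ", target, " values")
  sort(v)[ceiling(length(v) / 2)]
}

#' Label reactions above/below a threshold
#'
#' Assigns label 1 iff the target value strictly exceeds the threshold;
#' records with the value exactly at the threshold get label 0. Records
#' missing the target value are excluded (their count is reported).
#'
#' @param records clean record data.frame.
#' @param spec a [label_spec()].
#' @return a `labeled_reactions` object: `records`, `labels` (0/1 integer),
#'   `label_spec`, `n_excluded`.
#' @export
label_reactions <- function(records, spec = label_spec("yield")) {
  stopifnot(inherits(spec, "label_spec"))
  val <- if (spec$target == "yield") records$yield_pct else records$time_h
  keep <- !is.na(val)
  if (!any(keep)) stop("no labelable records (all missing ", spec$target, ")")
  v <- val[keep]
  if (!(min(v) < spec$threshold && spec$threshold < max(v))) {
    stop("threshold ", spec$threshold, " is not strictly inside the observed ",
         spec$target, " range [", min(v), ", ", max(v), "]")
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(list(records = out,
                 labels = as.integer(v > spec$threshold),
                 label_spec = spec,
                 n_excluded = sum(!keep)),
            class = "labeled_reactions")
}

#' @export
print.labeled_reactions <- function(x, ...) {
  cat("<labeled_reactions> ", nrow(x$records), " records (",
      sum(x$labels == 1L), " positive / ", sum(x$labels == 0L), " negative, ",
      x$n_excluded, " excluded)\n", sep = "")
  print(x$label_spec)
  invisible(x)
}

#' Write a labeled dataset / rejection log
#'
#' @param labeled a `labeled_reactions` object.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_labeled_csv <- function(labeled, path) {
  stopifnot(inherits(labeled, "labeled_reactions"))
  df <- labeled$records
  df$label <- labeled$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @param rejects rejection data.frame from [clean_reactions()].
#' @rdname write_labeled_csv
#' @export
write_rejects_jsonl <- function(rejects, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(rejects))) {
    writeLines(jsonlite::toJSON(as.list(rejects[i, , drop = FALSE][1, ]),
                                auto_unbox = TRUE), con)
  }
  invisible(path)
}
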