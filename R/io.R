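#' Read a compound table
#'
#' Accepts the canonical two-column CSV/TSV with a header naming a
#' \code{smiles} and a \code{label} column, or headerless whitespace-
#' delimited text (SMILES then endpoint), the format used by classic
#' correlation-weight tools.  Labels must be 0 or 1; offending rows are
#' reported with their line numbers.
#'
#' @param path Input file.
#' @return Data frame with columns \code{smiles} (character) and
#'   \code{label} (integer 0/1).
#' @export
read_compounds <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty input file: ", path)
  has_header <- grepl("smiles", tolower(first), fixed = TRUE)
  if (has_header) {
    sep <- if (grepl(",", first, fixed = TRUE)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            quote = "\"", comment.char = "",
                            stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    if (!all(c("smiles", "label") %in% names(df)))
      stop("header must name 'smiles' and 'label' columns: ", path)
    off <- 1L
  } else {
    df <- utils::read.table(path, header = FALSE, comment.char = "",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("need two columns (SMILES, endpoint): ", path)
    names(df)[1:2] <- c("smiles", "label")
    off <- 0L
  }
  lab <- suppressWarnings(as.numeric(df$label))
  bad <- which(is.na(lab) | !(lab %in% c(0, 1)))
  if (length(bad))
    stop(sprintf("non-binary labels on line(s) %s of %s",
                 paste(utils::head(bad + off, 10L), collapse = ", "), path))
  data.frame(smiles = as.character(df$smiles), label = as.integer(lab),
             stringsAsFactors = FALSE)
}

#' Write a compound table as the canonical CSV
#'
#' @param data Data frame with \code{smiles} and \code{label} columns.
#' @param path Output file.
#' @export
write_compounds <- function(data, path) {
  utils::write.csv(data[intersect(c("smiles", "label", "true_score"),
                                  names(data))],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

file_md5 <- function(x) unname(tools::md5sum(x))

data_md5 <- function(data) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(data$smiles, data$label, sep = "\t"), tmp)
  file_md5(tmp)
}

write_manifest <- function(path, manifest) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

split_membership <- function(split) {
  data.frame(
    compound = unlist(split[split_sets], use.names = FALSE),
    subset = rep(split_sets, times = lengths(split[split_sets])),
    stringsAsFactors = FALSE)
}

#' Train one semi-correlation model on a fresh random split
#'
#' End-to-end single-split run: draws one four-way random split, runs the
#' Monte Carlo optimization with the calibration overtraining guard, and
#' assembles a per-set classification report (confusion counts plus
#' sensitivity, specificity, accuracy, MCC, and a Total row).  When
#' \code{out_dir} is given, the model, epoch history, report, split
#' membership and a JSON run manifest (config echo, seeds, input checksum,
#' vocabulary size, chosen epoch) are written there, enough to re-execute
#' the run bit-identically.
#'
#' @param data Compound table (data frame with \code{smiles}, \code{label})
#'   or a path readable by [read_compounds()].
#' @param config An [optimizer_config()]; its seed drives the split, the
#'   weight initialization and the move stream.
#' @param out_dir Optional output directory (created if missing).
#' @return Invisibly, a list with \code{fit} (the \code{"mc_fit"}),
#'   \code{model}, \code{report}, \code{split} and \code{manifest}.
#' @export
run_train <- function(data, config = optimizer_config(), out_dir = NULL) {
  input_path <- NULL
  if (is.character(data)) {
    input_path <- data
    data <- read_compounds(data)
  }
  split <- make_splits(nrow(data), k = 1L, seed = config$seed)[[1]]
  fit <- mc_optimize(data, split, config)
  pred <- predict(fit$model, data$smiles)
  membership <- split_membership(split)
  set_of <- character(nrow(data))
  set_of[membership$compound] <- membership$subset
  report <- classification_report(data$label, pred$category, set_of,
                                  set_order = split_sets)
  manifest <- list(
    tool = "semicor::run_train",
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    input_md5 = if (is.null(input_path)) data_md5(data) else
      file_md5(input_path),
    n_compounds = nrow(data),
    vocabulary_size = fit$vocabulary_size,
    chosen_epoch = fit$chosen_epoch)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_model(fit$model, file.path(out_dir, "model.txt"))
    utils::write.csv(fit$history, file.path(out_dir, "history.csv"),
                     row.names = FALSE)
    utils::write.csv(report, file.path(out_dir, "report.csv"),
                     row.names = FALSE)
    utils::write.csv(membership, file.path(out_dir, "split.csv"),
                     row.names = FALSE)
    write_manifest(file.path(out_dir, "manifest.json"), manifest)
  }
  invisible(list(fit = fit, model = fit$model, report = report,
                 split = split, manifest = manifest))
}

#' Train and cross-validate a system of self-consistent models
#'
#' Draws k independent four-way splits, trains one model per split (each
#' with its own derived seed), and assembles the k x k cross-split MCC
#' matrix: entry (i, j) is model i's MCC on split j's validation set.  The
#' off-diagonal mean and population dispersion summarise how robust the
#' modelling protocol is to the random split; the Jaccard overlap matrix of
#' the validation sets shows how distinct the k assessments are.
#'
#' @inheritParams run_train
#' @param k Number of splits/models (>= 2).
#' @return Invisibly, a list with \code{models}, \code{fits},
#'   \code{splits}, \code{matrix} (consistency matrix), \code{summary}
#'   (off-diagonal mean/sd, all-cells mean), \code{overlap} and
#'   \code{manifest}.
#' @export
run_self_consistent <- function(data, config = optimizer_config(), k = 5L,
                                out_dir = NULL) {
  if (k < 2L) stop("k >= 2 required for self-consistency")
  input_path <- NULL
  if (is.character(data)) {
    input_path <- data
    data <- read_compounds(data)
  }
  splits <- make_splits(nrow(data), k = k, seed = config$seed)
  fits <- vector("list", k)
  for (i in seq_len(k)) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0("model", i))
    fits[[i]] <- mc_optimize(data, splits[[i]], cfg)
  }
  models <- lapply(fits, `[[`, "model")
  mat <- build_matrix(models, splits, data)
  summary <- summarize_consistency(mat)
  overlap <- validation_overlap(splits)
  manifest <- list(
    tool = "semicor::run_self_consistent",
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config), k = k,
    input_md5 = if (is.null(input_path)) data_md5(data) else
      file_md5(input_path),
    n_compounds = nrow(data),
    chosen_epochs = vapply(fits, `[[`, integer(1), "chosen_epoch"),
    summary = summary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(k)) {
      write_model(models[[i]], file.path(out_dir,
                                         sprintf("model_%d.txt", i)))
      utils::write.csv(split_membership(splits[[i]]),
                       file.path(out_dir, sprintf("split_%d.csv", i)),
                       row.names = FALSE)
    }
    utils::write.csv(as.data.frame(unclass(mat)),
                     file.path(out_dir, "consistency_matrix.csv"))
    utils::write.csv(as.data.frame(overlap),
                     file.path(out_dir, "validation_overlap.csv"))
    write_manifest(file.path(out_dir, "summary.json"),
                   c(summary, list(k = k)))
    write_manifest(file.path(out_dir, "manifest.json"), manifest)
  }
  invisible(list(models = models, fits = fits, splits = splits,
                 matrix = mat, summary = summary, overlap = overlap,
                 manifest = manifest))
}

#' Predict activity for a file of SMILES
#'
#' @param model A \code{"semicor_model"} or path to a model file.
#' @param smiles Character vector of SMILES, or a path: either a compound
#'   table readable by [read_compounds()] or plain text with one SMILES
#'   per line.
#' @param out_path Optional CSV output path.
#' @return Data frame: smiles, dcw, y, category, unknown_attributes.
#' @export
predict_file <- function(model, smiles, out_path = NULL) {
  if (is.character(model)) model <- read_model(model)
  stopifnot(inherits(model, "semicor_model"))
  if (length(smiles) == 1L && file.exists(smiles)) {
    first <- tolower(readLines(smiles, n = 1L))
    smiles <- if (grepl("smiles", first, fixed = TRUE))
      read_compounds(smiles)$smiles else readLines(smiles)
  }
  out <- predict(model, smiles)
  if (!is.null(out_path)) {
    utils::write.csv(out, out_path, row.names = FALSE)
  }
  out
}
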