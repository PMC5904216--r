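## File formats and configuration.
##
## Time series travel in a long (tidy) CSV with columns
## sample_id, time, variable, value — one row per observed measurement.
## Long format is the only unambiguous choice for irregular sampling: a
## wide table would have to invent a common grid.  Labels travel in a
## second CSV keyed by sample_id (one label column, or several for
## multi-task problems).  Times are plain reals in caller-chosen units; no
## calendar parsing.

#' Read a long-format measurement CSV into a dataset
#'
#' Per sample, the union of observation times becomes the stamp vector
#' (shifted so the first stamp is 0); variables observed at a stamp get
#' mask 1, everything else is missing; intervals are derived by
#' [compute_time_interval()].
#'
#' @param path CSV with header `sample_id,time,variable,value`.
#' @param variables optional character vector fixing the variable set and
#'   column order; unknown variables in the file raise an error.
#' @return an unlabeled `ts_dataset`.
#' @export
read_long_csv <- function(path, variables = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "variable", "value")
  if (!all(need %in% names(df)))
    stop("long CSV must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0) stop("empty long CSV: no measurements")
  dup <- duplicated(df[, c("sample_id", "time", "variable")])
  if (any(dup))
    stop("duplicate (sample_id, time, variable) at data line(s): ",
         paste(utils::head(which(dup), 5), collapse = ", "))
  if (is.null(variables)) variables <- sort(unique(df$variable))
  if (!all(df$variable %in% variables))
    stop("unknown variable(s): ",
         paste(setdiff(unique(df$variable), variables), collapse = ", "))
  D <- length(variables)
  ids <- unique(df$sample_id)
  samples <- lapply(ids, function(id) {
    sub <- df[df$sample_id == id, ]
    stamps <- sort(unique(sub$time))
    stamps0 <- stamps - stamps[1]
    raw <- matrix(NA_real_, length(stamps), D)
    ti <- match(sub$time, stamps)
    vi <- match(sub$variable, variables)
    raw[cbind(ti, vi)] <- sub$value
    ts_sample(raw, stamps0, sample_id = as.character(id))
  })
  ts_dataset(samples, variable_names = variables)
}

#' Write a dataset as a long-format measurement CSV
#'
#' Only observed entries are written; the file round-trips through
#' [read_long_csv()] (values at full precision, masks exactly).
#'
#' @param dataset a `ts_dataset`.
#' @param path output path.
#' @export
write_long_csv <- function(dataset, path) {
  rows <- lapply(dataset$samples, function(s) {
    obs <- which(s$mask == 1, arr.ind = TRUE)
    if (nrow(obs) == 0) return(NULL)
    data.frame(sample_id = s$sample_id,
               time = s$stamps[obs[, 1]],
               variable = dataset$variable_names[obs[, 2]],
               value = s$values[cbind(obs[, 1], obs[, 2])])
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$sample_id, df$time, df$variable), ]
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a label CSV
#'
#' Column `sample_id` plus one or more label columns.  With one label
#' column a vector is attached; with several, a binary matrix (multi-task).
#'
#' @param dataset a `ts_dataset` whose sample ids the labels are matched to.
#' @param path label CSV path.
#' @return the dataset with labels attached.
#' @export
attach_labels <- function(dataset, path) {
  lab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(lab)) stop("label CSV needs a sample_id column")
  ids <- vapply(dataset$samples, function(s) s$sample_id, character(1))
  pos <- match(ids, as.character(lab$sample_id))
  if (anyNA(pos)) stop("missing labels for sample(s): ",
                       paste(utils::head(ids[is.na(pos)], 5), collapse = ", "))
  cols <- setdiff(names(lab), "sample_id")
  labels <- if (length(cols) == 1) lab[pos, cols]
            else as.matrix(lab[pos, cols])
  dataset$labels <- labels
  dataset
}

#' Write labels next to a long CSV
#' @param dataset labeled `ts_dataset`.
#' @param path output path.
#' @export
write_labels_csv <- function(dataset, path) {
  ids <- vapply(dataset$samples, function(s) s$sample_id, character(1))
  lab <- dataset$labels
  df <- if (is.matrix(lab)) {
    cn <- colnames(lab) %||% paste0("task", seq_len(ncol(lab)))
    cbind(data.frame(sample_id = ids), as.data.frame(lab) |>
            stats::setNames(cn))
  } else data.frame(sample_id = ids, label = lab)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save / load a model checkpoint
#'
#' Checkpoints are JSON objects holding every named parameter array (keyed
#' by symbol name) plus the head, normalization statistics and config, so
#' they can be loaded from any language with a JSON parser.
#'
#' @param model a fitted `grud_model`.
#' @param path output path (`.json`).
#' @export
write_checkpoint <- function(model, path) {
  obj <- list(
    mode = model$mode,
    params = serialize_params(model$params),
    head = list(kind = model$head$kind, n_out = model$head$n_out,
                batch_norm = model$head$batch_norm,
                dropout = model$head$dropout,
                W = list(dim = dim(model$head$W),
                         data = as.numeric(model$head$W)),
                b = model$head$b, bn = model$head$bn),
    norm_stats = list(mean = model$norm_stats$mean, sd = model$norm_stats$sd,
                      provenance = model$norm_stats$provenance),
    empirical_means = as.numeric(model$empirical_means),
    variant = unclass(model$variant),
    config = unclass(model$config)
  )
  obj$config$variant <- unclass(obj$config$variant)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_checkpoint
#' @return `read_checkpoint()` returns the restored `grud_model`.
#' @export
read_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- deserialize_params(obj$params)
  head <- obj$head
  head$W <- matrix(head$W$data, head$W$dim[1], head$W$dim[2])
  head$b <- as.numeric(head$b)
  if (isTRUE(head$batch_norm)) {
    head$bn <- lapply(head$bn, function(x)
      if (is.numeric(x)) as.numeric(x) else x)
  } else head$bn <- NULL
  cfg <- obj$config
  cfg$variant <- do.call(simple_variant, as.list(cfg$variant))
  class(cfg) <- "model_config"
  ns <- structure(list(mean = as.numeric(obj$norm_stats$mean),
                       sd = as.numeric(obj$norm_stats$sd),
                       provenance = obj$norm_stats$provenance),
                  class = "norm_stats")
  structure(list(params = params, head = head, norm_stats = ns,
                 empirical_means = as.numeric(obj$empirical_means),
                 config = cfg, mode = obj$mode,
                 variant = do.call(simple_variant, as.list(obj$variant)),
                 history = NULL, best_valid_auc = NA_real_),
            class = "grud_model")
}

#' Read a JSON run configuration
#'
#' Keys mirror the arguments of [model_config()] and [synthetic_config()];
#' unknown keys raise an error.
#'
#' @param path JSON file.
#' @param kind `"model"` or `"synthetic"`.
#' @return a `model_config` or `synthetic_config`.
#' @export
read_config <- function(path, kind = c("model", "synthetic")) {
  kind <- match.arg(kind)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ctor <- if (kind == "model") model_config else synthetic_config
  known <- names(formals(ctor))
  bad <- setdiff(names(obj), known)
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(ctor, obj)
}

log_line <- function(...) {
  kv <- list(...)
  msg <- paste(sprintf("%s=%s", names(kv), unlist(kv)), collapse = " ")
  message(msg)
}
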