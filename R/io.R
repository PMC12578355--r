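# Plain-text readers and writers: cohort directories, windowed feature
# tables (CSV + manifest JSON), and model checkpoints (JSON at 17
# significant digits, which round-trips doubles bit-exactly).

#' Write a cohort to a directory tree
#'
#' One directory per subject with `attributes.json`, `labels.csv`
#' (time_s, code) and one `<channel>.csv` (time_s, value) per channel, plus
#' a top-level `cohort_manifest.json` recording subjects, rates and the
#' generating configuration.
#'
#' @param cohort list of `subject_record`s.
#' @param path output directory.
#' @param config optional `cohort_config` to record in the manifest.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, config = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort) {
    sd <- file.path(path, s$subject_id)
    dir.create(sd, showWarnings = FALSE)
    jsonlite::write_json(s$attributes, file.path(sd, "attributes.json"),
                         auto_unbox = TRUE)
    lr <- s$labels$sampling_rate
    write.csv(data.frame(time_s = (seq_along(s$labels$codes) - 1) / lr,
                         code = s$labels$codes),
              file.path(sd, "labels.csv"), row.names = FALSE)
    for (ch in s$channels) {
      write.csv(data.frame(time_s = (seq_along(ch$samples) - 1) /
                             ch$sampling_rate,
                           value = ch$samples),
                file.path(sd, paste0(ch$name, ".csv")), row.names = FALSE)
    }
  }
  manifest <- list(
    subjects = vapply(cohort, `[[`, "", "subject_id"),
    rates = as.list(vapply(cohort[[1]]$channels, `[[`, numeric(1),
                           "sampling_rate")),
    label_rate_hz = cohort[[1]]$labels$sampling_rate,
    schedule = if (!is.null(config)) config$state_schedule,
    seed = if (!is.null(config)) config$seed)
  jsonlite::write_json(manifest, file.path(path, "cohort_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param path cohort directory.
#' @return list of `subject_record`s.
#' @export
read_cohort <- function(path) {
  mf <- jsonlite::fromJSON(file.path(path, "cohort_manifest.json"))
  lapply(mf$subjects, function(sid) {
    sd <- file.path(path, sid)
    attrs <- jsonlite::fromJSON(file.path(sd, "attributes.json"))
    lab <- read.csv(file.path(sd, "labels.csv"))
    channels <- list()
    for (ch in names(mf$rates)) {
      d <- read.csv(file.path(sd, paste0(ch, ".csv")))
      channels[[ch]] <- list(name = ch, sampling_rate = mf$rates[[ch]],
                             samples = d$value)
    }
    structure(list(subject_id = sid, attributes = attrs,
                   channels = channels,
                   labels = list(sampling_rate = mf$label_rate_hz,
                                 codes = as.integer(lab$code))),
              class = "subject_record")
  })
}

#' Write / read the windowed feature table
#'
#' CSV with header `subject_id, window_index, label, <feature names...>`
#' (attributes first, then indicator features in manifest order), plus a
#' sidecar `<path>.manifest.json` holding the feature manifest. Values are
#' written at 17 significant digits so the round trip is exact to well below
#' 1e-12.
#'
#' @param features_list list of `feature_set`s.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features_list, path) {
  rows <- do.call(rbind, lapply(features_list, function(fs) {
    data.frame(subject_id = fs$subject_id,
               window_index = seq_along(fs$labels),
               label = fs$labels,
               as.data.frame(fs$PF, check.names = FALSE),
               check.names = FALSE)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(rows), collapse = ","), con)
  num <- vapply(rows, is.numeric, logical(1)) &
    !(colnames(rows) %in% c("window_index", "label"))
  fmt <- rows
  for (j in which(num)) fmt[[j]] <- sprintf("%.17g", rows[[j]])
  writeLines(do.call(paste, c(unname(fmt), sep = ",")), con)
  jsonlite::write_json(features_list[[1]]$manifest,
                       paste0(path, ".manifest.json"))
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  mf <- jsonlite::fromJSON(paste0(path, ".manifest.json"))
  manifest <- list(attributes = mf$attributes,
                   indicators = lapply(mf$indicators, identity))
  tab <- read.csv(path, check.names = FALSE)
  needed <- c(manifest$attributes, unlist(manifest$indicators))
  missing <- setdiff(needed, colnames(tab))
  if (length(missing))
    stop_data("feature table is missing column(s): ",
              paste(missing, collapse = ", "))
  lapply(split(tab, tab$subject_id), function(d) {
    d <- d[order(d$window_index), ]
    PF <- as.matrix(d[, needed, drop = FALSE])
    rownames(PF) <- NULL
    B <- lapply(manifest$indicators, function(cols)
      PF[, cols, drop = FALSE])
    structure(list(subject_id = d$subject_id[1], B = B,
                   A = PF[1, manifest$attributes],
                   PF = PF, labels = as.integer(d$label),
                   manifest = manifest),
              class = "feature_set")
  })
}

CHECKPOINT_VERSION <- "affectsig-checkpoint-1"

#' Save / load a model checkpoint
#'
#' A single JSON document holding the version header, model configuration,
#' feature manifest, normalisation statistics and every parameter array
#' under named keys (`contrib.<indicator>.W1`, ..., `analyser.G2`,
#' `baseline.u`). Doubles are written at 17 significant digits, so
#' save -> load -> forward reproduces the original forward pass bit for bit.
#'
#' @param model an `affect_model` (or `affect_fit`; its model is saved).
#' @param path file path.
#' @return `path` invisibly (save); the restored `affect_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  model <- model_of(model)
  params <- flatten_params(model)
  norms <- list()
  for (ind in model$indicators) {
    norms[[paste0("contrib.", ind)]] <- model$contrib[[ind]]$norm
    norms[[paste0("affect.", ind)]] <- model$affect[[ind]]$norm
  }
  doc <- list(version = CHECKPOINT_VERSION,
              config = unclass(model$config),
              manifest = model$manifest,
              norms = norms,
              params = params)
  writeLines(jsonlite::toJSON(doc, digits = I(17), auto_unbox = FALSE,
                              pretty = FALSE), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e)
                    stop_data("cannot parse checkpoint: ", conditionMessage(e)))
  if (!identical(as.character(doc$version), CHECKPOINT_VERSION))
    stop_data("checkpoint version mismatch: found ", doc$version %||% "none")
  cfg <- doc$config
  mconfig <- model_config(cfg$contrib_hidden, cfg$affect_hidden,
                          cfg$affect_depth, cfg$analyser_hidden,
                          cfg$n_classes, cfg$seed)
  manifest <- list(attributes = doc$manifest$attributes,
                   indicators = lapply(doc$manifest$indicators, identity))
  model <- init_model(mconfig, manifest)
  params <- doc$params
  tmpls <- flatten_params(model)
  # jsonlite restores matrices with their dims; coerce vectors explicitly
  for (nm in names(params)) {
    tmpl <- tmpls[[nm]]
    if (is.null(tmpl)) stop_data("unknown parameter key in checkpoint: ", nm)
    p <- params[[nm]]
    if (is.matrix(tmpl)) p <- matrix(as.numeric(p), nrow(tmpl), ncol(tmpl))
    else p <- as.numeric(p)
    params[[nm]] <- p
  }
  model <- set_params(model, params)
  for (ind in model$indicators) {
    cn <- doc$norms[[paste0("contrib.", ind)]]
    an <- doc$norms[[paste0("affect.", ind)]]
    model$contrib[[ind]]$norm <- list(mean = as.numeric(cn$mean),
                                      var = as.numeric(cn$var),
                                      initialized = as.logical(cn$initialized))
    model$affect[[ind]]$norm <- list(mean = as.numeric(an$mean),
                                     var = as.numeric(an$var),
                                     initialized = as.logical(an$initialized))
  }
  model
}
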