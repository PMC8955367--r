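# Orchestration, file I/O and reproducibility plumbing ------------------------

#' Write epochs to a plain array container with a JSON sidecar
#'
#' Each epoch is one tab-delimited samples x channels text file; the sidecar
#' records rate, channel labels, labels and seed so a round trip restores the
#' dataset.
#'
#' @param dataset an `epoch_dataset` from [generate_dataset()], or a list of
#'   [multichannel_epoch()].
#' @param dir output directory (created).
#' @param labels condition labels when `dataset` is a bare list.
#' @param seed optional seed recorded in the sidecar.
#' @return `dir`, invisibly.
#' @export
write_epochs <- function(dataset, dir, labels = NULL, seed = NULL) {
  if (inherits(dataset, "epoch_dataset")) {
    epochs <- dataset$epochs; labels <- as.character(dataset$labels)
  } else {
    epochs <- dataset
    labels <- if (is.null(labels)) rep(NA_character_, length(epochs))
              else as.character(labels)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("epoch_%04d.tsv", seq_along(epochs))
  for (i in seq_along(epochs)) {
    utils::write.table(epochs[[i]]$data, file.path(dir, files[i]),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  sidecar <- list(rate = epochs[[1]]$rate, channels = epochs[[1]]$channels,
                  files = files, labels = labels, seed = seed)
  jsonlite::write_json(sidecar, file.path(dir, "epochs.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read epochs from a plain array container
#'
#' @param dir directory written by [write_epochs()].
#' @return an `epoch_dataset`.
#' @export
read_epochs <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "epochs.json"),
                              simplifyVector = TRUE)
  epochs <- lapply(side$files, function(f) {
    m <- as.matrix(utils::read.table(file.path(dir, f), header = TRUE,
                                     sep = "\t", check.names = FALSE))
    multichannel_epoch(m, side$rate, side$channels)
  })
  labels <- side$labels
  structure(list(epochs = epochs,
                 labels = factor(labels, levels = unique(labels)),
                 channels = side$channels, rate = side$rate),
            class = "epoch_dataset")
}

#' Read a multichannel recording from a delimited array container
#'
#' Reads a samples x channels delimited text file with a header of channel
#' labels, drops reference channels (M1/M2) if present, checks the remaining
#' labels against the montage and reorders the columns to canonical montage
#' order.
#'
#' @param path file path (tab- or comma-delimited, header row of labels).
#' @param rate sampling rate in Hz.
#' @param montage expected channel labels (default the 62-channel 10-20
#'   montage).
#' @param drop reference labels to discard (default M1, M2).
#' @return a [multichannel_epoch()] spanning the whole recording.
#' @export
read_recording <- function(path, rate, montage = montage_1020(),
                           drop = c("M1", "M2")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = sep,
                                   check.names = FALSE))
  m <- m[, !(colnames(m) %in% drop), drop = FALSE]
  unknown <- setdiff(colnames(m), montage)
  if (length(unknown))
    stop("unknown channel labels: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(montage, colnames(m))
  if (length(missing))
    stop("missing montage channels: ", paste(missing, collapse = ", "),
         call. = FALSE)
  multichannel_epoch(m[, montage, drop = FALSE], rate, montage)
}

#' Write a labelled square matrix as delimited text
#'
#' @param x a [plv_matrix()], [binary_network()] or labelled matrix.
#' @param path output path.
#' @export
write_matrix_labeled <- function(x, path) {
  m <- if (inherits(x, "plv_matrix")) x$values
       else if (inherits(x, "binary_network")) x$adjacency
       else as.matrix(x)
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read a labelled square matrix written by [write_matrix_labeled()]
#'
#' @param path input path.
#' @return labelled numeric matrix.
#' @export
read_matrix_labeled <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1, check.names = FALSE))
  m
}

#' Export a binary network as an edge list
#'
#' @param net a [binary_network()].
#' @param path output path (two tab-separated label columns, one edge per
#'   line, each undirected edge once).
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "binary_network"))
  idx <- which(upper.tri(net$adjacency) & net$adjacency == 1, arr.ind = TRUE)
  df <- data.frame(node1 = net$node_labels[idx[, 1]],
                   node2 = net$node_labels[idx[, 2]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end pipeline; a config plus its seeds
#' reproduces a run's decisions (thresholds, rankings, splits) exactly.
#'
#' @param bands character vector of band names to analyze (default theta,
#'   alpha, beta; gamma is excluded by default because narrowband PLV there
#'   is too low to threshold robustly).
#' @param montage channel labels.
#' @param n_surrogates,alpha surrogate-threshold settings.
#' @param edge_trim seconds trimmed at epoch ends before phase averaging.
#' @param normalization,invert_weights WKPN settings (see
#'   [node_importance()]).
#' @param n_repetitions,train_frac,cost classifier settings.
#' @param feature_length `m` passed to [build_features()] (`NULL` = all).
#' @param seed master integer seed.
#' @param out_dir run directory.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(bands = c("theta", "alpha", "beta"),
                            montage = montage_1020(),
                            n_surrogates = 200, alpha = 0.05,
                            edge_trim = 0.25,
                            normalization = "sum", invert_weights = FALSE,
                            n_repetitions = 20, train_frac = 0.6, cost = 1,
                            feature_length = NULL,
                            seed = 1, out_dir = tempfile("wkpnet_run_")) {
  structure(list(bands = bands, montage = montage,
                 n_surrogates = n_surrogates, alpha = alpha,
                 edge_trim = edge_trim, normalization = normalization,
                 invert_weights = invert_weights,
                 n_repetitions = n_repetitions, train_frac = train_frac,
                 cost = cost, feature_length = feature_length,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline on a labelled epoch collection
#'
#' For each configured band: band-filters every epoch, computes its PLV
#' matrix, derives one pooled surrogate threshold for the band, binarizes,
#' ranks node importance per epoch network (WKPN plus WDC/WPR comparators on
#' the same networks), assembles feature datasets and evaluates the SVM on
#' repeated stratified 3:2 splits. Every intermediate artifact is written
#' under `config$out_dir` together with a structured log carrying the config
#' hash and the thresholds actually applied.
#'
#' @param config a [pipeline_config()].
#' @param dataset an `epoch_dataset` (e.g. from [generate_dataset()] or
#'   [read_epochs()]); alternatively epochs are read from
#'   `file.path(config$out_dir, "input")`.
#' @return list of per-band results: `threshold`, `networks`, `profiles`,
#'   `reports` (one `eval_report` per ranking method), invisibly also written
#'   to disk.
#' @export
run_pipeline <- function(config, dataset = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(dataset))
    dataset <- read_epochs(file.path(config$out_dir, "input"))
  if (!identical(dataset$channels, config$montage))
    stop("dataset montage does not match config montage", call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(config)
  jsonlite::write_json(c(unclass(config), list(config_hash = hash)),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  bands <- default_bands(config$bands)
  log_lines <- c(sprintf("config_hash\t%s", hash),
                 sprintf("seed\t%d", config$seed),
                 sprintf("n_epochs\t%d", length(dataset$epochs)))
  results <- list()
  for (b in names(bands)) {
    band <- bands[[b]]
    bdir <- file.path(config$out_dir, b)
    dir.create(bdir, showWarnings = FALSE)
    filtered <- lapply(dataset$epochs, band_filter, band = band)
    thr <- surrogate_threshold(filtered, band = NULL,
                               n_surrogates = config$n_surrogates,
                               alpha = config$alpha,
                               seed = config$seed,
                               edge_trim = config$edge_trim)
    thr$band <- band$name
    log_lines <- c(log_lines,
                   sprintf("%s\tthreshold\t%.6f", b, thr$threshold))
    plvs <- lapply(seq_along(filtered), function(i) {
      p <- plv_matrix(filtered[[i]], band = NULL,
                      edge_trim = config$edge_trim, epoch_id = i)
      p$band <- band$name
      write_matrix_labeled(p, file.path(bdir, sprintf("plv_%04d.tsv", i)))
      p
    })
    nets <- lapply(seq_along(plvs), function(i) {
      nt <- binarize(plvs[[i]], thr,
                     condition = as.character(dataset$labels[i]))
      write_edge_list(nt, file.path(bdir, sprintf("network_%04d.tsv", i)))
      nt
    })
    profiles <- lapply(nets, node_importance,
                       normalization = config$normalization,
                       invert_weights = config$invert_weights)
    jsonlite::write_json(
      lapply(profiles, function(p) list(Q = as.list(p$Q), d = p$d,
                                        ranking = p$ranking)),
      file.path(bdir, "profiles.json"), auto_unbox = TRUE, digits = NA)
    ds_wkpn <- build_features(profiles, dataset$labels,
                              m = config$feature_length, band = b,
                              method = "wkpn")
    ds_wdc <- build_features(lapply(nets, wdc), dataset$labels,
                             m = config$feature_length, band = b,
                             method = "wdc")
    ds_wpr <- build_features(lapply(nets, wpr), dataset$labels,
                             m = config$feature_length, band = b,
                             method = "wpr")
    reports <- compare_methods(list(wkpn = ds_wkpn, wdc = ds_wdc,
                                    wpr = ds_wpr),
                               n_repetitions = config$n_repetitions,
                               seed = config$seed,
                               train_frac = config$train_frac,
                               cost = config$cost)
    jsonlite::write_json(
      lapply(reports, function(r) list(mean_accuracy = r$mean_accuracy,
                                       accuracies = r$accuracies,
                                       n_repetitions = r$n_repetitions,
                                       seed = r$seed)),
      file.path(bdir, "reports.json"), auto_unbox = TRUE, digits = NA)
    for (meth in names(reports)) {
      log_lines <- c(log_lines, sprintf("%s\taccuracy_%s\t%.4f", b, meth,
                                        reports[[meth]]$mean_accuracy))
    }
    results[[b]] <- list(threshold = thr, plv = plvs, networks = nets,
                         profiles = profiles, reports = reports)
  }
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  invisible(results)
}
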