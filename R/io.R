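# --- model-definition files, CSV exports, run manifests --------------------

fmt_num <- function(x) {
  # 12 significant digits, plain notation where possible, for reproducible
  # text outputs
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    format(v, digits = 12, scientific = FALSE, trim = TRUE)
  }, "")
}

model_to_list <- function(net) {
  nz <- function(m) {
    out <- list()
    for (from in rownames(m)) {
      row <- m[from, ]
      row <- row[row != 0]
      if (length(row)) out[[from]] <- as.list(row)
    }
    out
  }
  out <- list(
    nodes = as.list(net$nodes),
    signals = as.list(net$signals),
    regulator_pair = as.list(net$regulators),
    omega = nz(net$omega),
    omega0 = as.list(net$omega0),
    sigma = as.list(net$sigma),
    gamma = as.list(net$gamma),
    signal_omega = nz(net$signal_omega))
  if (!is.null(net$polarizing)) out$polarizing_pair <- as.list(net$polarizing)
  if (!is.null(net$saturation)) out$saturation <- net$saturation
  out
}

#' Write a model-definition file
#'
#' Serialises an influence network to YAML or JSON (chosen by the file
#' extension). Interaction and signal weights are written as nested maps
#' from source to target, omitting absent (zero) influences.
#'
#' @param net an \code{\link{influence_network}} or a
#'   \code{\link{get_model}} bundle (its network is written).
#' @param path output file; extension \code{.yaml}/\code{.yml} or
#'   \code{.json}.
#' @return \code{path}, invisibly.
#' @export
write_model <- function(net, path) {
  if (inherits(net, "model_bundle")) net <- net$network
  if (!inherits(net, "influence_network"))
    stop("`net` must be an influence_network or model_bundle", call. = FALSE)
  lst <- model_to_list(net)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(lst, path, precision = 15)
  } else if (ext == "json") {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else stop("unsupported extension '.", ext, "' (use .yaml or .json)",
              call. = FALSE)
  invisible(path)
}

cfg_err <- function(field, msg) {
  stop("model configuration field `", field, "`: ", msg, call. = FALSE)
}

as_num1 <- function(x, field) {
  x <- suppressWarnings(as.numeric(x))
  if (length(x) != 1L || is.na(x)) cfg_err(field, "must be a single number")
  x
}

#' Read a model-definition file
#'
#' Parses and validates a YAML or JSON model definition written by
#' \code{\link{write_model}} (or by hand). Validation is strict: unknown
#' top-level keys, unknown node/signal names inside the weight maps,
#' nonpositive \code{sigma}/\code{gamma} and malformed entries are all
#' rejected with the offending field named. A signal listed under
#' \code{signals} but missing from \code{signal_omega} simply contributes
#' zero weights (reported via a message).
#'
#' @param path the file to read.
#' @return an \code{\link{influence_network}}.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path)
  else stop("unsupported extension '.", ext, "'", call. = FALSE)

  allowed <- c("nodes", "signals", "regulator_pair", "polarizing_pair",
               "omega", "omega0", "sigma", "gamma", "signal_omega",
               "saturation")
  unknown <- setdiff(names(lst), allowed)
  if (length(unknown))
    stop("unknown model configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  nodes <- as.character(unlist(lst$nodes))
  if (!length(nodes)) cfg_err("nodes", "at least one node is required")
  signals <- as.character(unlist(lst$signals))

  per_node <- function(field, default = NULL, positive = FALSE) {
    v <- lst[[field]]
    out <- stats::setNames(numeric(length(nodes)), nodes)
    if (is.null(v)) {
      if (is.null(default)) cfg_err(field, "is required")
      out[] <- default
      return(out)
    }
    if (is.null(names(v)) || !all(names(v) %in% nodes))
      cfg_err(field, "must be a map keyed by node names")
    for (nm in names(v)) out[nm] <- as_num1(v[[nm]], paste0(field, ".", nm))
    if (positive && any(out <= 0))
      cfg_err(field, "entries must be > 0")
    out
  }

  nested <- function(field, rows, cols) {
    m <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
    v <- lst[[field]]
    if (is.null(v)) return(m)
    bad_from <- setdiff(names(v), rows)
    if (length(bad_from))
      cfg_err(field, paste0("unknown source name(s): ",
                            paste(bad_from, collapse = ", ")))
    for (from in names(v)) {
      row <- v[[from]]
      bad_to <- setdiff(names(row), cols)
      if (length(bad_to))
        cfg_err(paste0(field, ".", from),
                paste0("unknown target node(s): ",
                       paste(bad_to, collapse = ", ")))
      for (to in names(row))
        m[from, to] <- as_num1(row[[to]], paste0(field, ".", from, ".", to))
    }
    m
  }

  omega <- nested("omega", nodes, nodes)
  so <- nested("signal_omega", signals, nodes)
  if (length(signals)) {
    missing_rows <- setdiff(signals, names(lst$signal_omega %||% list()))
    if (length(missing_rows))
      message("signal(s) without weights default to zero: ",
              paste(missing_rows, collapse = ", "))
  }
  sat <- lst$saturation
  if (!is.null(sat))
    sat <- lapply(sat, function(el) list(smax = as_num1(el$smax, "saturation.smax"),
                                         K = as_num1(el$K, "saturation.K")))

  influence_network(
    nodes = nodes, signals = signals, omega = omega,
    omega0 = per_node("omega0", default = 0),
    sigma = per_node("sigma", default = 1, positive = TRUE),
    gamma = per_node("gamma", default = 1, positive = TRUE),
    signal_omega = so,
    regulators = if (!is.null(lst$regulator_pair))
      as.character(unlist(lst$regulator_pair)) else NULL,
    polarizing = if (!is.null(lst$polarizing_pair))
      as.character(unlist(lst$polarizing_pair)) else NULL,
    saturation = sat)
}

write_csv_text <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  out <- df
  out[num] <- lapply(df[num], fmt_num)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a trajectory as CSV
#' @param traj a \code{\link{integrate_network}} trajectory.
#' @param path output file.
#' @export
write_trajectory_csv <- function(traj, path)
  write_csv_text(as.data.frame(traj), path)

#' Export steady states as CSV
#' @param ss a \code{\link{find_steady_states}} result.
#' @param path output file.
#' @export
write_steady_states_csv <- function(ss, path) {
  df <- as.data.frame(ss)
  ev <- attr(ss, "eigenvalues")
  if (!is.null(ev) && length(ev) == nrow(df)) {
    df$eigenvalues <- vapply(ev, function(z)
      paste(fmt_num(Re(z)), collapse = ";"), "")
  }
  write_csv_text(df, path)
}

#' Export a continuation branch as CSV
#'
#' Columns: arclength, the free parameter, one column per state variable,
#' stability, and (where a special point was refined between samples) its
#' kind.
#' @param branch a \code{\link{trace_branch}} result.
#' @param path output file.
#' @export
write_branch_csv <- function(branch, path) {
  df <- branch$samples
  df$special_point_kind <- ""
  sp <- branch$special_points
  if (nrow(sp)) {
    for (k in seq_len(nrow(sp))) {
      i <- which.min(abs(df[[2]] - sp[[2]][k]))
      df$special_point_kind[i] <- sp$kind[k]
    }
  }
  write_csv_text(df, path)
}

#' Export a stability map or bidirectional diagram as long-format CSV
#'
#' Columns: the two axis values, \code{n_stable} and \code{signature}
#' (sorted stable-phenotype labels joined by \code{"+"}). For a
#' bidirectional diagram the lower half's axis-2 values are negated.
#' @param x a \code{stability_map} or \code{bidirectional_diagram}.
#' @param path output file.
#' @export
write_map_csv <- function(x, path) {
  map_df <- function(m, flip = FALSE) {
    g <- expand.grid(i = seq_along(m$axis1$values), j = seq_along(m$axis2$values))
    data.frame(axis1 = m$axis1$values[g$i],
               axis2 = (if (flip) -1 else 1) * m$axis2$values[g$j],
               n_stable = m$n_stable[cbind(g$i, g$j)],
               signature = m$signature[cbind(g$i, g$j)])
  }
  df <- if (inherits(x, "bidirectional_diagram")) {
    rbind(map_df(x$upper), map_df(x$lower, flip = TRUE))
  } else map_df(x)
  names(df)[1:2] <- if (inherits(x, "bidirectional_diagram"))
    c(x$upper$axis1$name, "polarizing") else c(x$axis1$name, x$axis2$name)
  write_csv_text(df, path)
}

#' Export a composition grid as CSV
#'
#' One row per grid point with the phenotype counts, derived fractions and
#' (optionally) heterogeneity-score columns.
#'
#' @param grid a \code{\link{composition_grid}}.
#' @param path output file.
#' @param scores named list of phenotype subsets; each adds a score column
#'   \code{SH_<name>}.
#' @export
write_composition_csv <- function(grid, path,
                                  scores = list(XSP_YSP = c("XSP", "YSP"))) {
  g <- expand.grid(i = seq_along(grid$axis1$values),
                   j = seq_along(grid$axis2$values))
  df <- data.frame(axis1 = grid$axis1$values[g$i],
                   axis2 = grid$axis2$values[g$j])
  names(df) <- c(grid$axis1$name, grid$axis2$name)
  for (ph in dimnames(grid$counts)[[3]])
    df[[paste0("n_", ph)]] <- grid$counts[, , ph][cbind(g$i, g$j)]
  for (ph in dimnames(grid$counts)[[3]])
    df[[paste0("frac_", ph)]] <-
      grid$counts[, , ph][cbind(g$i, g$j)] / grid$n_cells
  for (nm in names(scores)) {
    sc <- score_grid(grid, scores[[nm]])
    df[[paste0("SH_", nm)]] <- sc[cbind(g$i, g$j)]
  }
  write_csv_text(df, path)
}

#' Read a composition CSV
#'
#' Reads a file written by \code{\link{write_composition_csv}} (or any CSV
#' with \code{n_naive}, \code{n_XSP}, \code{n_YSP}, \code{n_DP} columns)
#' back into a data frame of compositions.
#' @param path the CSV file.
#' @return data frame.
#' @export
read_composition_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- paste0("n_", c("naive", "XSP", "YSP", "DP"))
  if (!all(need %in% names(df)))
    stop("composition CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' Write a run manifest
#'
#' Every command-line run emits one manifest recording the command, model
#' and provenance, overrides, seeds, package version and the files written,
#' so outputs can be reproduced bit-identically from the recorded seeds.
#'
#' @param path output JSON file.
#' @param command the subcommand run.
#' @param model model name (or \code{NA}).
#' @param provenance model provenance string.
#' @param overrides named list of parameter overrides.
#' @param seed integer seed (or \code{NA}).
#' @param outputs character vector of files written.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(path, command, model = NA, provenance = NA,
                           overrides = list(), seed = NA,
                           outputs = character()) {
  manifest <- list(command = command, model = model, provenance = provenance,
                   overrides = overrides, seed = seed,
                   tool = "hetdiff",
                   version = as.character(utils::packageVersion("hetdiff")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   outputs = as.list(outputs))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(path)
}
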