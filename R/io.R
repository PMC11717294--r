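landmark_csv_header <- function() {
  c("t", paste0(rep(c("x", "y"), 21), rep(0:20, each = 2)),
    "ux1", "uy1", "ux2", "uy2", "lx1", "ly1", "lx2", "ly2", "source")
}

#' Write a landmark sequence
#'
#' CSV schema: one row per frame with columns `t`, the 42 landmark
#' coordinates `x0,y0,...,x20,y20`, the 8 chopstick endpoint coordinates
#' and the per-frame detection `source`. The JSON format stores the same
#' content as one object per frame plus sequence metadata (label,
#' archetype, seed, fps).
#'
#' @param sequence a `grip_sequence`.
#' @param path output file; format chosen by extension unless `format`
#'   is given.
#' @param format `"csv"` or `"json"`.
#' @return invisibly, `path`.
#' @export
write_landmark_series <- function(sequence, path,
                                  format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "csv") {
    df <- data.frame(t = sequence$t, sequence$landmarks,
                     sequence$chopsticks, source = sequence$source,
                     check.names = FALSE)
    colnames(df) <- landmark_csv_header()
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    n <- length(sequence$t)
    frames <- lapply(seq_len(n), function(i) list(
      t = sequence$t[i],
      points = matrix(sequence$landmarks[i, ], ncol = 2, byrow = TRUE),
      chopsticks = as.numeric(sequence$chopsticks[i, ]),
      source = sequence$source[i]))
    jsonlite::write_json(
      list(meta = list(label = sequence$label, archetype = sequence$archetype,
                       fps = sequence$protocol$fps, seed = sequence$seed,
                       handedness = sequence$handedness),
           frames = frames),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' Read a landmark sequence
#'
#' Parses the CSV or JSON schema written by [write_landmark_series()],
#' ordering frames by time and reporting schema violations with the
#' offending row/frame number.
#'
#' @param path input file.
#' @return a `grip_sequence` (with a reconstructed protocol; noise and
#'   dropout settings are not recoverable from data files).
#' @export
read_landmark_series <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    frames <- obj$frames
    pts <- frames$points
    for (i in seq_along(pts)) {
      p <- pts[[i]]
      if (is.null(dim(p)) || nrow(p) != 21 || ncol(p) != 2)
        stopf("frame %d has %s points; expected 21", i,
              if (is.null(dim(p))) "malformed" else nrow(p))
    }
    n <- length(pts)
    lm <- t(vapply(pts, function(p) as.vector(t(p)), numeric(42)))
    ch <- frames$chopsticks
    chop <- if (is.matrix(ch)) ch else do.call(rbind, lapply(ch, as.numeric))
    tvec <- as.numeric(frames$t)
    src <- as.character(frames$source)
    meta <- obj$meta
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
    expect <- landmark_csv_header()
    if (!identical(colnames(df), expect)) {
      nbad <- ncol(df) - 2 - 8  # coordinate columns present
      stopf("landmark CSV schema mismatch: %d coordinate columns imply %s points (expected 21); header row invalid",
            max(nbad, 0), max(nbad, 0) / 2)
    }
    tvec <- df$t
    lm <- as.matrix(df[, 2:43])
    chop <- as.matrix(df[, 44:51])
    src <- as.character(df$source)
    meta <- list(label = NA_character_, archetype = NA_character_,
                 fps = NULL, seed = NULL, handedness = "right")
  }
  ord <- order(tvec)
  lm <- lm[ord, , drop = FALSE]; chop <- chop[ord, , drop = FALSE]
  tvec <- tvec[ord]; src <- src[ord]
  n <- length(tvec)
  fps <- meta$fps %||%
    (if (n > 1) round(1 / stats::median(diff(tvec))) else 30)
  colnames(lm) <- landmark_csv_header()[2:43]
  colnames(chop) <- landmark_csv_header()[44:51]
  proto <- trial_protocol(duration_s = n / fps, fps = fps,
                          noise_sd_px = NA_real_, dropout_rate = 0)
  structure(list(t = tvec, landmarks = lm, valid = matrix(TRUE, n, 21),
                 chopsticks = chop, source = src, truth = NULL,
                 label = meta$label %||% NA_character_,
                 archetype = meta$archetype %||% NA_character_,
                 protocol = proto, seed = meta$seed,
                 handedness = meta$handedness %||% "right"),
            class = "grip_sequence")
}

#' Write / read tracked chopstick poses
#'
#' CSV schema: `frame, ux1, uy1, ux2, uy2, lx1, ly1, lx2, ly2, source`.
#'
#' @param poses list of [chopstick_pose()] (e.g. from
#'   [track_sequence()]).
#' @param path CSV file.
#' @return `write_pose_series` returns `path` invisibly;
#'   `read_pose_series` returns a list of `chopstick_pose`.
#' @export
write_pose_series <- function(poses, path) {
  df <- data.frame(
    frame = vapply(poses, function(p) as.integer(p$frame_index), 0L),
    t(vapply(poses, function(p) c(p$upper, p$lower), numeric(8))),
    source = vapply(poses, function(p) p$source, ""))
  colnames(df) <- c("frame", "ux1", "uy1", "ux2", "uy2",
                    "lx1", "ly1", "lx2", "ly2", "source")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pose_series
#' @export
read_pose_series <- function(path) {
  df <- utils::read.csv(path)
  lapply(seq_len(nrow(df)), function(i)
    chopstick_pose(as.numeric(df[i, 2:5]), as.numeric(df[i, 6:9]),
                   df$source[i], df$frame[i]))
}

#' Write / read per-frame grip features
#'
#' CSV schema: `t, a, b, c, d`, the 42 landmark coordinates, the 8
#' chopstick coordinates, `filled`, `missing`.
#'
#' @param features a `grip_features` object.
#' @param path CSV file.
#' @return `write_feature_series` returns `path` invisibly;
#'   `read_feature_series` returns a `grip_features`.
#' @export
write_feature_series <- function(features, path) {
  df <- data.frame(t = features$t, features$feats, features$landmark_xy,
                   features$chopstick_xy, filled = features$filled,
                   missing = features$missing, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_series
#' @export
read_feature_series <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  n <- nrow(df)
  structure(list(t = df$t,
                 feats = as.matrix(df[, c("a", "b", "c", "d")]),
                 landmark_xy = as.matrix(df[, 6:47]),
                 chopstick_xy = as.matrix(df[, 48:55]),
                 filled = as.logical(df$filled),
                 missing = as.logical(df$missing),
                 fps = if (n > 1) 1 / stats::median(diff(df$t)) else NA_real_,
                 label = NA_character_, archetype = NA_character_,
                 normalized = "none"),
            class = "grip_features")
}

# rpart classification tree -> plain nested list (binary tree, node ids in
# the rpart 2i/2i+1 numbering; continuous splits only, no surrogates)
rpart_to_list <- function(fit) {
  fr <- fit$frame
  ids <- as.integer(row.names(fr))
  ylev <- attr(fit, "ylevels")
  splits <- fit$splits
  split_row <- integer(nrow(fr))
  split_row[fr$var != "<leaf>"] <- seq_len(sum(fr$var != "<leaf>"))
  build <- function(id) {
    i <- match(id, ids)
    if (fr$var[i] == "<leaf>") {
      nlev <- length(ylev)
      probs <- as.numeric(fr$yval2[i, (nlev + 2):(2 * nlev + 1)])
      return(list(leaf = TRUE, class = ylev[fr$yval[i]],
                  prob = stats::setNames(probs, ylev), n = fr$n[i]))
    }
    sp <- splits[split_row[i], ]
    list(leaf = FALSE, var = as.character(fr$var[i]),
         threshold = unname(sp["index"]),
         left_if_less = unname(sp["ncat"]) < 0,
         left = build(2 * id), right = build(2 * id + 1))
  }
  build(1L)
}

predict_tree_list <- function(node, x) {
  while (!isTRUE(node$leaf)) {
    v <- x[[node$var]]
    go_left <- if (node$left_if_less) v < node$threshold else v >= node$threshold
    node <- if (go_left) node$left else node$right
  }
  node
}

#' Serialize / load a grip classifier as JSON
#'
#' The model file stores the tree structure (nodes, split variables and
#' thresholds, leaf class fractions), the retained features, importances,
#' configuration and a configuration hash, so a saved model can classify
#' new summaries without refitting.
#'
#' @param model a [grip_classifier()] fit.
#' @param path JSON file.
#' @return `write_grip_model` returns `path` invisibly;
#'   `read_grip_model` returns a `grip_classifier` whose tree is the
#'   deserialized node list (predictions are identical to the original
#'   fit's).
#' @export
write_grip_model <- function(model, path) {
  stopifnot(inherits(model, "grip_classifier"))
  tree <- if (inherits(model$tree, "rpart")) rpart_to_list(model$tree)
          else model$tree
  payload <- list(type = "grip_classifier",
                  retained = model$retained,
                  importance = as.list(model$importance),
                  config = model$config,
                  feature_names = model$feature_names,
                  levels = model$levels,
                  tree = tree)
  payload$config_hash <- config_hash(jsonlite::toJSON(payload$config,
                                                      auto_unbox = TRUE))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_grip_model
#' @export
read_grip_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$type, "grip_classifier"))
    stopf("not a grip classifier model file: %s", path)
  fix_node <- function(nd) {
    if (isTRUE(nd$leaf)) {
      nd$prob <- unlist(nd$prob)
      return(nd)
    }
    nd$left <- fix_node(nd$left); nd$right <- fix_node(nd$right)
    nd
  }
  structure(list(tree = structure(fix_node(obj$tree), class = "grip_tree_nodes"),
                 retained = unlist(obj$retained),
                 importance = unlist(obj$importance),
                 config = obj$config,
                 feature_names = unlist(obj$feature_names),
                 levels = unlist(obj$levels)),
            class = "grip_classifier")
}

#' Write survey records to CSV, or read them back
#'
#' A column-mapping configuration (named character vector,
#' `canonical = "file column"`) adapts external survey sheets to the
#' canonical schema of [make_survey_table()].
#'
#' @param records survey data frame.
#' @param path CSV file.
#' @param mapping optional named character vector renaming file columns
#'   to canonical names on read.
#' @return `write_survey_table` returns `path` invisibly;
#'   `read_survey_table` returns the records data frame.
#' @export
write_survey_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survey_table
#' @export
read_survey_table <- function(path, mapping = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    miss <- setdiff(unname(mapping), colnames(df))
    if (length(miss))
      stopf("mapped column(s) absent from file: %s", paste(miss, collapse = ", "))
    for (canon in names(mapping))
      colnames(df)[colnames(df) == mapping[[canon]]] <- canon
  }
  df
}

#' Write stage results plus a reproducibility manifest
#'
#' Writes each result (data frames as CSV, everything else as JSON) into
#' `dir` and a `manifest.json` recording the written files, the
#' configuration and its hash, the seed and tool versions, enabling
#' exact re-runs.
#'
#' @param results named list of results.
#' @param dir output directory (created if needed).
#' @param config configuration list recorded in the manifest.
#' @param seed seed recorded in the manifest.
#' @return invisibly, the manifest path.
#' @export
write_outputs <- function(results, dir, config = list(), seed = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x)) {
      f <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(x, f, row.names = FALSE)
    } else {
      f <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA,
                           na = "null", force = TRUE)
    }
    files <- c(files, basename(f))
  }
  manifest <- list(files = files,
                   config = config,
                   config_hash = config_hash(jsonlite::toJSON(config,
                                                              auto_unbox = TRUE)),
                   seed = seed,
                   r_version = as.character(getRversion()),
                   package_version =
                     as.character(utils::packageVersion("chopgrip")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}
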