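#' Construct a tracking series
#'
#' An epoch-level trace of one animal: time `t` in seconds since experiment
#' start (strictly increasing, uniformly spaced by `epoch_s`), longitudinal
#' position `x` in mm from the food end (food = 0), and `vmax`, the maximal
#' velocity within each epoch in mm/s. Positions slightly outside the tube
#' are flagged (column `out_of_tube`), not dropped: they are tracker
#' artefacts worth keeping visible.
#'
#' @param t,x,vmax Numeric vectors of equal length.
#' @param animal_id Identifier.
#' @param epoch_s Epoch length, seconds.
#' @param tube_length_mm Physical tube length (default 70).
#' @param lights_on_s Offset of ZT0 in seconds relative to `t = 0`.
#' @param tol Positional tolerance (mm) before a sample is flagged.
#' @return A `tracking_series` data frame.
#' @export
tracking_series <- function(t, x, vmax, animal_id, epoch_s,
                            tube_length_mm = 70, lights_on_s = 0, tol = 1) {
  df <- data.frame(t = as.numeric(t), x = as.numeric(x),
                   vmax = as.numeric(vmax))
  validate_tracking(df, animal_id, epoch_s)
  if (any(vmax < 0)) {
    stop(sprintf("tracking series '%s': vmax must be >= 0", animal_id))
  }
  out <- x < -tol | x > tube_length_mm + tol
  if (any(out)) {
    warning(sprintf("tracking series '%s': %d positions outside the tube (flagged)",
                    animal_id, sum(out)))
    df$out_of_tube <- out
  }
  structure(df,
            animal_id = animal_id, epoch_s = epoch_s,
            tube_length_mm = tube_length_mm, lights_on_s = lights_on_s,
            class = c("tracking_series", "data.frame"))
}

# internal fast path used by the simulator (data already well-formed)
new_tracking_series <- function(ep, cfg, animal_id, bouts = NULL,
                                indiv_scale = NULL) {
  structure(ep,
            animal_id = animal_id, epoch_s = cfg$epoch_s,
            tube_length_mm = cfg$tube_length_mm, lights_on_s = cfg$lights_on_s,
            bouts = bouts, indiv_scale = indiv_scale,
            class = c("tracking_series", "data.frame"))
}

validate_tracking <- function(df, animal_id, epoch_s) {
  t <- df$t
  if (anyDuplicated(t)) {
    d <- t[duplicated(t)][1]
    stop(sprintf("tracking series '%s': duplicated timestamp t = %g",
                 animal_id, d))
  }
  if (is.unsorted(t, strictly = TRUE)) {
    stop(sprintf("tracking series '%s': t must be strictly increasing", animal_id))
  }
  if (length(t) > 1) {
    dt <- diff(t)
    if (any(abs(dt - epoch_s) > 1e-6)) {
      i <- which(abs(dt - epoch_s) > 1e-6)[1]
      stop(sprintf(
        "tracking series '%s': non-uniform epoch spacing at t = %g (gap of %g s, expected %g s)",
        animal_id, t[i], dt[i], epoch_s
      ))
    }
  }
  invisible(df)
}

#' @export
print.tracking_series <- function(x, ...) {
  cat(sprintf(
    "<tracking_series> %s: %d epochs of %gs (%.4g h), tube %g mm\n",
    attr(x, "animal_id"), nrow(x), attr(x, "epoch_s"),
    nrow(x) * attr(x, "epoch_s") / 3600, attr(x, "tube_length_mm")
  ))
  print(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat(sprintf("... %d more epochs\n", nrow(x) - 4L))
  invisible(x)
}

#' Construct a stimulus (tube-rotation) log
#'
#' @param animal_id Identifier (recycled).
#' @param t_onset Rotation onset times, seconds; strictly increasing per
#'   animal.
#' @param duration Rotation durations, seconds (default 1).
#' @return A `stimulus_log` data frame.
#' @export
stimulus_log <- function(animal_id, t_onset, duration = rep(1, length(t_onset))) {
  df <- data.frame(
    animal_id = rep_len(animal_id, length(t_onset)),
    t_onset = as.numeric(t_onset),
    duration = as.numeric(duration),
    stringsAsFactors = FALSE
  )
  for (id in unique(df$animal_id)) {
    on <- df$t_onset[df$animal_id == id]
    if (is.unsorted(on, strictly = TRUE)) {
      stop(sprintf("stimulus log '%s': onsets must be strictly increasing", id))
    }
  }
  structure(df, class = c("stimulus_log", "data.frame"))
}

#' Zeitgeber time of experiment timestamps
#'
#' ZT (hours since lights-on, modulo 24) of times `t` in seconds since
#' experiment start: `((t - lights_on_s) / 3600) %% 24`. All modules bin time
#' through this mapping, with half-open intervals `[start, end)` and day
#' boundaries at ZT0.
#'
#' @param t Seconds since experiment start.
#' @param lights_on_s Offset of ZT0 in seconds.
#' @return ZT in `[0, 24)` hours.
#' @export
zt_hours <- function(t, lights_on_s = 0) ((t - lights_on_s) / 3600) %% 24

#' @rdname zt_hours
#' @export
zt_day <- function(t, lights_on_s = 0) floor((t - lights_on_s) / 86400)

#' Write/read tracking data as CSV with a JSON sidecar
#'
#' The canonical interchange format is a plain CSV with columns
#' `animal_id,t,x,vmax` plus a JSON sidecar (`<path>.json`) recording
#' `epoch_s`, `tube_length_mm` and `lights_on_s` — inspectable with any
#' spreadsheet, diffable, and self-describing.
#'
#' @param series A `tracking_series` or list of them.
#' @param path CSV file path.
#' @return `write_tracking()` returns `path` invisibly; `read_tracking()`
#'   returns a named list of `tracking_series`, one per `animal_id`.
#' @export
write_tracking <- function(series, path) {
  if (inherits(series, "tracking_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    data.frame(animal_id = attr(s, "animal_id"), t = s$t, x = s$x,
               vmax = s$vmax, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  s1 <- series[[1]]
  sidecar <- list(
    format = "ethosleep-tracking-v1",
    epoch_s = attr(s1, "epoch_s"),
    tube_length_mm = attr(s1, "tube_length_mm"),
    lights_on_s = attr(s1, "lights_on_s"),
    animals = vapply(series, attr, "", "animal_id")
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_tracking
#' @param epoch_s,tube_length_mm,lights_on_s Used only when no sidecar is
#'   found next to `path`.
#' @export
read_tracking <- function(path, epoch_s = 10, tube_length_mm = 70,
                          lights_on_s = 0) {
  if (!file.exists(path)) stop(sprintf("no such tracking file: %s", path))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    epoch_s <- meta$epoch_s
    tube_length_mm <- meta$tube_length_mm
    lights_on_s <- meta$lights_on_s
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "t", "x", "vmax")
  if (!all(need %in% names(df))) {
    stop(sprintf("tracking file must declare columns %s",
                 paste(need, collapse = ", ")))
  }
  ids <- unique(df$animal_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$animal_id == id, , drop = FALSE]
    tracking_series(sub$t, sub$x, sub$vmax, id, epoch_s,
                    tube_length_mm = tube_length_mm, lights_on_s = lights_on_s)
  })
  names(out) <- ids
  out
}

#' Write/read stimulus logs and animal metadata as CSV
#'
#' @param stim A `stimulus_log`.
#' @param path CSV path.
#' @export
write_stimuli <- function(stim, path) {
  utils::write.csv(as.data.frame(stim), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stimuli
#' @export
read_stimuli <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stimulus_log(df$animal_id, df$t_onset,
               if ("duration" %in% names(df)) df$duration else rep(1, nrow(df)))
}

#' @rdname write_stimuli
#' @param meta A data frame of per-animal metadata (`animal_id`, `sex`,
#'   `treatment`, and optionally `trigger_s`, `lights_on_s`, `mated`,
#'   `death_t`, `censored`).
#' @export
write_metadata <- function(meta, path) {
  utils::write.csv(as.data.frame(meta), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stimuli
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"animal_id" %in% names(df)) stop("metadata must have an animal_id column")
  if ("death_t" %in% names(df) && any(!is.na(df$death_t) & df$death_t <= 0)) {
    stop("metadata: death_t must be > 0 when present")
  }
  df
}

#' Converter stub for native ethoscope databases
#'
#' The native SQLite dialect of the upstream video-tracking platform is out
#' of scope; export to the CSV interchange format instead.
#' @param path Ignored.
#' @export
read_ethoscope_db <- function(path) {
  stop("unsupported dialect: native ethoscope SQLite databases are not read; export to tracking CSV instead")
}

#' Serialize a UPGMA dendrogram to Newick
#'
#' Writes the tree produced by [upgma()] as a Newick string with branch
#' lengths derived from the ultrametric node heights (a node sits at half its
#' merge distance, so the cophenetic distance between two leaves equals their
#' merge distance).
#'
#' @param tree An object returned by [upgma()].
#' @param path Optional file path; if `NULL` the string is returned only.
#' @return The Newick string, invisibly if written to `path`.
#' @export
#' @examples
#' d <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
#' write_newick(upgma(d)) # "(a:1,b:1);"
write_newick <- function(tree, path = NULL) {
  labels <- tree$labels
  if (anyDuplicated(labels)) {
    stop(sprintf("duplicate leaf name: %s", labels[duplicated(labels)][1]))
  }
  fmt <- function(v) sprintf("%.10g", v)
  if (length(labels) == 1L) {
    s <- sprintf("%s:0;", labels[1])
  } else {
    hgt <- tree$height / 2 # ultrametric node heights
    node_str <- function(id) {
      # id < 0: leaf -id at height 0; id > 0: internal node id
      if (id < 0) list(str = labels[-id], h = 0)
      else {
        a <- node_str(tree$merge[id, 1])
        b <- node_str(tree$merge[id, 2])
        h <- hgt[id]
        list(str = sprintf("(%s:%s,%s:%s)", a$str, fmt(h - a$h),
                           b$str, fmt(h - b$h)), h = h)
      }
    }
    s <- paste0(node_str(nrow(tree$merge))$str, ";")
  }
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}
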