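# Sequence file I/O.
#
# CSV dialect: one row per (sequence, frame, joint) with columns
#   sequence_id, subject_id, emotion, repetition, frame_index, timestamp_s,
#   joint_name, px, py, pz, ox, oy, oz [, space]
# ox..oz are empty when the joint has no orientation. The optional trailing
# `space` column records the coordinate-space tag for transformed
# sequences; absent means sensor space. UTF-8, '.' decimal.
#
# JSON-lines: one object per frame:
#   {"sequence_id":..., "subject_id":..., "emotion":..., "repetition":...,
#    "frame_index":..., "timestamp_s":..., "space":...,
#    "joints": {"SpineBase": {"p":[x,y,z], "o":[x,y,z]|null}, ...}}

#' Read skeletal motion sequences
#'
#' Parses a CSV or JSON-lines file in the documented 25-joint skeletal
#' schema into a list of [motion_sequence()] objects. Joints with missing
#' orientation are stored as `NA`, never zero. Malformed rows (wrong joint
#' count, non-numeric fields) and unknown joint names raise errors naming
#' the offending frame.
#'
#' @param path file path.
#' @param format `"csv"` or `"jsonl"`; inferred from the extension if
#'   missing.
#' @return list of `motion_sequence`.
#' @export
read_sequences <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$|\\.ndjson$", path)) "jsonl" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") read_sequences_csv(path) else read_sequences_jsonl(path)
}

read_sequences_csv <- function(path) {
  dt <- data.table::fread(path, colClasses = list(
    character = c("sequence_id", "subject_id", "emotion", "joint_name")
  ), showProgress = FALSE)
  req <- c("sequence_id", "subject_id", "emotion", "repetition",
           "frame_index", "timestamp_s", "joint_name",
           "px", "py", "pz", "ox", "oy", "oz")
  missing_cols <- setdiff(req, names(dt))
  if (length(missing_cols)) {
    stop("malformed skeletal CSV; missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(dt) == 0) return(list())
  bad <- !dt$joint_name %in% .joint_names
  if (any(bad)) {
    stop("unknown joint name '", dt$joint_name[which(bad)[1]],
         "' at row ", which(bad)[1], call. = FALSE)
  }
  for (col in c("timestamp_s", "px", "py", "pz")) {
    if (!is.numeric(dt[[col]])) {
      stop("non-numeric values in column ", col, call. = FALSE)
    }
    if (anyNA(dt[[col]])) {
      stop("missing/non-numeric value in column ", col, " at row ",
           which(is.na(dt[[col]]))[1], call. = FALSE)
    }
  }
  for (col in c("ox", "oy", "oz")) {
    if (is.logical(dt[[col]])) dt[[col]] <- as.numeric(dt[[col]])
    if (is.character(dt[[col]])) {
      dt[[col]] <- suppressWarnings(as.numeric(dt[[col]]))
    }
  }
  has_space <- "space" %in% names(dt)
  seq_ids <- unique(dt$sequence_id)
  lapply(seq_ids, function(sid) {
    d <- dt[dt$sequence_id == sid, ]
    frames <- sort(unique(d$frame_index))
    nf <- length(frames)
    pos <- array(NA_real_, c(nf, 25, 3))
    ori <- array(NA_real_, c(nf, 25, 3))
    ts <- numeric(nf)
    for (k in seq_len(nf)) {
      fd <- d[d$frame_index == frames[k], ]
      if (nrow(fd) != 25 || anyDuplicated(fd$joint_name)) {
        stop("sequence ", sid, " frame ", frames[k], " has ", nrow(fd),
             " joint rows (expected 25 distinct joints)", call. = FALSE)
      }
      j <- joint_index(fd$joint_name)
      pos[k, j, ] <- cbind(fd$px, fd$py, fd$pz)
      ori[k, j, ] <- cbind(fd$ox, fd$oy, fd$oz)
      ts[k] <- fd$timestamp_s[1]
    }
    # orientation rows with any NA are treated as absent
    incomplete <- apply(is.na(ori), c(1, 2), any)
    ori[rep(incomplete, 3)] <- NA_real_
    motion_sequence(
      positions = pos, timestamps = ts,
      subject = d$subject_id[1], emotion = d$emotion[1],
      repetition = d$repetition[1], orientations = ori,
      space = if (has_space) d$space[1] else "sensor",
      sequence_id = sid
    )
  })
}

read_sequences_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(list())
  recs <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) {
      stop("malformed JSON at line ", i, ": ", conditionMessage(e),
           call. = FALSE)
    })
    rec$.line <- i
    rec
  })
  ids <- vapply(recs, function(r) r$sequence_id, character(1))
  lapply(unique(ids), function(sid) {
    rs <- recs[ids == sid]
    ord <- order(vapply(rs, function(r) r$frame_index, numeric(1)))
    rs <- rs[ord]
    nf <- length(rs)
    pos <- array(NA_real_, c(nf, 25, 3))
    ori <- array(NA_real_, c(nf, 25, 3))
    ts <- numeric(nf)
    for (k in seq_len(nf)) {
      r <- rs[[k]]
      jn <- names(r$joints)
      if (length(jn) != 25 || !setequal(jn, .joint_names)) {
        unknown <- setdiff(jn, .joint_names)
        if (length(unknown)) {
          stop("unknown joint name '", unknown[1], "' at line ", r$.line,
               call. = FALSE)
        }
        stop("frame at line ", r$.line, " has ", length(jn),
             " joints (expected 25)", call. = FALSE)
      }
      for (nm in jn) {
        j <- joint_index(nm)
        p <- as.numeric(r$joints[[nm]]$p)
        if (length(p) != 3 || anyNA(p)) {
          stop("non-numeric position for ", nm, " at line ", r$.line,
               call. = FALSE)
        }
        pos[k, j, ] <- p
        o <- r$joints[[nm]]$o
        if (!is.null(o) && length(o) == 3 && !anyNA(as.numeric(o))) {
          ori[k, j, ] <- as.numeric(o)
        }
      }
      ts[k] <- r$timestamp_s
    }
    r1 <- rs[[1]]
    motion_sequence(
      positions = pos, timestamps = ts, subject = r1$subject_id,
      emotion = r1$emotion, repetition = r1$repetition,
      orientations = ori, space = r1$space %||% "sensor",
      sequence_id = sid
    )
  })
}

#' Write skeletal motion sequences
#'
#' Serialises sequences in the documented CSV or JSON-lines schema; the
#' output round-trips through [read_sequences()] with numeric agreement to
#' better than 1e-9. An empty corpus produces a valid header-only CSV (or
#' empty JSON-lines file).
#'
#' @param seqs list of `motion_sequence`.
#' @param path output file path.
#' @param format `"csv"` or `"jsonl"`.
#' @return invisibly, `path`.
#' @export
write_sequences <- function(seqs, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "csv") write_sequences_csv(seqs, path)
  else write_sequences_jsonl(seqs, path)
  invisible(path)
}

write_sequences_csv <- function(seqs, path) {
  cols <- c("sequence_id", "subject_id", "emotion", "repetition",
            "frame_index", "timestamp_s", "joint_name",
            "px", "py", "pz", "ox", "oy", "oz", "space")
  if (!length(seqs)) {
    data.table::fwrite(
      setNames(data.table::data.table(matrix(nrow = 0, ncol = length(cols))),
               cols),
      path)
    return(invisible(path))
  }
  parts <- lapply(seqs, function(s) {
    nf <- n_frames(s)
    data.table::data.table(
      sequence_id = s$sequence_id,
      subject_id = s$subject,
      emotion = s$emotion,
      repetition = s$repetition,
      frame_index = rep(seq_len(nf), each = 25),
      timestamp_s = rep(s$timestamps, each = 25),
      joint_name = rep(.joint_names, nf),
      px = as.vector(t(s$positions[, , 1])),
      py = as.vector(t(s$positions[, , 2])),
      pz = as.vector(t(s$positions[, , 3])),
      ox = as.vector(t(s$orientations[, , 1])),
      oy = as.vector(t(s$orientations[, , 2])),
      oz = as.vector(t(s$orientations[, , 3])),
      space = s$space
    )
  })
  data.table::fwrite(data.table::rbindlist(parts), path, na = "")
  invisible(path)
}

write_sequences_jsonl <- function(seqs, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (s in seqs) {
    for (k in seq_len(n_frames(s))) {
      joints <- setNames(lapply(seq_len(25), function(j) {
        o <- s$orientations[k, j, ]
        list(
          p = s$positions[k, j, ],
          o = if (anyNA(o)) NULL else o
        )
      }), .joint_names)
      rec <- list(
        sequence_id = s$sequence_id, subject_id = s$subject,
        emotion = s$emotion, repetition = s$repetition,
        frame_index = k, timestamp_s = s$timestamps[k],
        space = s$space, joints = joints
      )
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                  null = "null"), con)
    }
  }
  invisible(path)
}
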