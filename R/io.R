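# On-disk formats: TRC marker trajectories, STO-like angle tables, and a
# CSV dialect for orientation series. All plain text, tab-delimited where
# the format is tab-based, full double precision on write.

.fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read keypoint series as TRC
#'
#' Tab-delimited marker-trajectory format (header with
#' DataRate/NumFrames/NumMarkers, mm units). Invalid (misdetected) points
#' are written as blank fields and read back as invalid.
#'
#' @param kps a [keypoint_series()].
#' @param path file path.
#' @return `read_trc` returns a [keypoint_series()]; `write_trc` returns
#'   `path` invisibly.
#' @export
write_trc <- function(kps, path) {
  stopifnot(inherits(kps, "keypoint_series"))
  markers <- dimnames(kps$points)[[2L]]
  n <- length(kps$time)
  k <- length(markers)
  h1 <- paste("PathFileType", "4", "(X/Y/Z)", basename(path), sep = "\t")
  h2 <- paste("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
              "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames",
              sep = "\t")
  h3 <- paste(.fmt_num(kps$rate), .fmt_num(kps$rate), n, k, "mm",
              .fmt_num(kps$rate), 1, n, sep = "\t")
  h4 <- paste(c("Frame#", "Time",
                as.vector(rbind(markers, "", ""))), collapse = "\t")
  h5 <- paste(c("", "", paste0(rep(c("X", "Y", "Z"), k),
                               rep(seq_len(k), each = 3L))), collapse = "\t")
  rows <- vapply(seq_len(n), function(i) {
    vals <- character(3L * k)
    for (j in seq_len(k)) {
      cols <- (3L * (j - 1L) + 1L):(3L * j)
      vals[cols] <- if (kps$valid[i, j]) .fmt_num(kps$points[i, j, ]) else ""
    }
    paste(c(i, .fmt_num(kps$time[i]), vals), collapse = "\t")
  }, character(1))
  writeLines(c(h1, h2, h3, h4, h5, rows), path)
  invisible(path)
}

#' @rdname write_trc
#' @export
read_trc <- function(path) {
  lines <- readLines(path)
  meta <- strsplit(lines[3L], "\t", fixed = TRUE)[[1L]]
  rate <- as.numeric(meta[1L])
  n <- as.integer(meta[3L])
  k <- as.integer(meta[4L])
  markers <- strsplit(lines[4L], "\t", fixed = TRUE)[[1L]][-(1:2)]
  markers <- markers[nzchar(markers)]
  if (length(markers) != k) stop("malformed TRC marker header", call. = FALSE)
  body <- strsplit(lines[5L + seq_len(n)], "\t", fixed = TRUE)
  time <- numeric(n)
  pts <- array(NA_real_, c(n, k, 3L),
               dimnames = list(NULL, markers, c("x", "y", "z")))
  valid <- matrix(FALSE, n, k)
  for (i in seq_len(n)) {
    f <- body[[i]]
    length(f) <- 2L + 3L * k
    time[i] <- as.numeric(f[2L])
    v <- suppressWarnings(as.numeric(f[-(1:2)]))
    for (j in seq_len(k)) {
      cols <- (3L * (j - 1L) + 1L):(3L * j)
      if (all(is.finite(v[cols]))) {
        pts[i, j, ] <- v[cols]
        valid[i, j] <- TRUE
      } else {
        pts[i, j, ] <- 0
      }
    }
  }
  keypoint_series(time, pts, rate, valid = valid)
}

#' Write / read a joint-angle table as an STO-like file
#'
#' Tab-delimited table (time column plus named angle columns in degrees)
#' with a small header carrying the rate and trial metadata. Values round
#' trip exactly.
#'
#' @param tab a [joint_angle_table()].
#' @param path file path.
#' @return `read_sto` returns a [joint_angle_table()]; `write_sto` returns
#'   `path` invisibly.
#' @export
write_sto <- function(tab, path) {
  stopifnot(inherits(tab, "joint_angle_table"))
  chans <- setdiff(names(tab), c("time", "gimbal"))
  hdr <- c("joint_angles",
           "version=1",
           "inDegrees=yes",
           paste0("rate=", .fmt_num(attr(tab, "rate"))),
           paste0("method=", attr(tab, "method")),
           paste0("placement=", attr(tab, "placement")),
           paste0("movement=", attr(tab, "movement")),
           paste0("participant=", attr(tab, "participant")),
           paste0("nRows=", nrow(tab)),
           paste0("nColumns=", length(chans) + 2L),
           "endheader",
           paste(c("time", chans, "gimbal"), collapse = "\t"))
  M <- as.matrix(as.data.frame(tab)[, c("time", chans)])
  rows <- apply(M, 1L, function(r) paste(.fmt_num(r), collapse = "\t"))
  rows <- paste(rows, as.integer(tab$gimbal), sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_sto
#' @export
read_sto <- function(path) {
  lines <- readLines(path)
  end <- match("endheader", lines)
  if (is.na(end)) stop("malformed STO: no endheader", call. = FALSE)
  hdr <- lines[seq_len(end - 1L)]
  get <- function(key, default = NA_character_) {
    hit <- grep(paste0("^", key, "="), hdr, value = TRUE)
    if (length(hit)) sub(paste0("^", key, "="), "", hit[1L]) else default
  }
  cols <- strsplit(lines[end + 1L], "\t", fixed = TRUE)[[1L]]
  body <- lines[-(seq_len(end + 1L))]
  body <- body[nzchar(body)]
  M <- do.call(rbind, lapply(strsplit(body, "\t", fixed = TRUE), as.numeric))
  colnames(M) <- cols
  chans <- setdiff(cols, c("time", "gimbal"))
  joint_angle_table(M[, "time"],
                    as.data.frame(M[, chans, drop = FALSE]),
                    rate = as.numeric(get("rate")),
                    method = get("method"), placement = get("placement"),
                    movement = get("movement"),
                    participant = get("participant"),
                    gimbal = as.logical(M[, "gimbal"]))
}

#' Write / read an orientation series as CSV
#'
#' Long-format CSV with columns `time, segment, w, x, y, z`.
#'
#' @param os an [orientation_series()].
#' @param path file path.
#' @param rate sampling rate (Hz), required on read.
#' @return `read_orientation_csv` returns an [orientation_series()];
#'   `write_orientation_csv` returns `path` invisibly.
#' @export
write_orientation_csv <- function(os, path) {
  stopifnot(inherits(os, "orientation_series"))
  segs <- dimnames(os$quats)[[2L]]
  n <- length(os$time)
  df <- do.call(rbind, lapply(seq_along(segs), function(s) {
    data.frame(time = .fmt_num(os$time), segment = segs[s],
               w = .fmt_num(os$quats[, s, 1L]),
               x = .fmt_num(os$quats[, s, 2L]),
               y = .fmt_num(os$quats[, s, 3L]),
               z = .fmt_num(os$quats[, s, 4L]))
  }))
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_orientation_csv
#' @export
read_orientation_csv <- function(path, rate) {
  df <- read.table(path, sep = ",", header = TRUE,
                   colClasses = c("numeric", "character", rep("numeric", 4)))
  segs <- unique(df$segment)
  time <- sort(unique(df$time))
  n <- length(time)
  Q <- array(NA_real_, c(n, length(segs), 4L),
             dimnames = list(NULL, segs, NULL))
  for (s in seq_along(segs)) {
    sub <- df[df$segment == segs[s], ]
    sub <- sub[order(sub$time), ]
    Q[, s, ] <- as.matrix(sub[, c("w", "x", "y", "z")])
  }
  orientation_series(time, Q, rate)
}
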