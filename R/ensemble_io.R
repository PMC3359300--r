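#' Write a conformation ensemble as plain text
#'
#' Text dialect: comment lines with provenance (`# key value`), then per
#' snapshot a `# MCS <t>` header, N lines of `x y z` integer unwrapped
#' coordinates, and one `LOOP i j expiry` line per active loop bond.
#'
#' @param ensemble A `dl_ensemble`.
#' @param path Output path.
#' @param provenance Optional named list written into the header.
#' @export
write_ensemble <- function(ensemble, path, provenance = NULL) {
  stopifnot(inherits(ensemble, "dl_ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# dynloop ensemble",
               paste("# N", ensemble$N),
               paste("# interval", ensemble$interval)), con)
  for (key in names(provenance))
    writeLines(paste("#", key, format(provenance[[key]])), con)
  for (k in seq_len(ensemble$n_conformations)) {
    writeLines(paste("# MCS", format(ensemble$mcs[k], scientific = FALSE)), con)
    pos <- ensemble$positions[, , k]
    writeLines(paste(pos[, 1], pos[, 2], pos[, 3]), con)
    lp <- ensemble$loops[[k]]
    if (nrow(lp) > 0)
      writeLines(paste("LOOP", lp$i, lp$j,
                       format(lp$expiry, scientific = FALSE)), con)
  }
  invisible(path)
}

#' Read a plain-text conformation ensemble
#'
#' @param path File written by [write_ensemble()].
#' @return A `dl_ensemble`.
#' @export
read_ensemble <- function(path) {
  if (!file.exists(path)) stop("ensemble file not found: ", path)
  lines <- readLines(path)
  n_line <- grep("^# N ", lines, value = TRUE)
  if (length(n_line) == 0) stop("not a dynloop ensemble file (no '# N' header)")
  N <- as.integer(sub("^# N ", "", n_line[1]))
  int_line <- grep("^# interval ", lines, value = TRUE)
  interval <- if (length(int_line) > 0)
    suppressWarnings(as.integer(sub("^# interval ", "", int_line[1])))
  else NA_integer_
  starts <- grep("^# MCS ", lines)
  if (length(starts) == 0) stop("no snapshots in ensemble file")
  snapshots <- lapply(seq_along(starts), function(s) {
    from <- starts[s] + 1
    to <- if (s < length(starts)) starts[s + 1] - 1 else length(lines)
    body <- lines[from:to]
    body <- body[!grepl("^#", body)]
    loop_rows <- grepl("^LOOP ", body)
    coords <- body[!loop_rows]
    if (length(coords) != N)
      stop("snapshot ", s, " has ", length(coords), " coordinate lines, expected ", N)
    pos <- matrix(as.integer(unlist(strsplit(coords, "[ \t]+"))),
                  ncol = 3, byrow = TRUE)
    lp <- body[loop_rows]
    loops <- if (length(lp) > 0) {
      f <- strsplit(sub("^LOOP ", "", lp), "[ \t]+")
      data.frame(i = as.integer(vapply(f, `[`, "", 1)),
                 j = as.integer(vapply(f, `[`, "", 2)),
                 expiry = as.numeric(vapply(f, `[`, "", 3)))
    } else data.frame(i = integer(0), j = integer(0), expiry = numeric(0))
    list(mcs = as.numeric(sub("^# MCS ", "", lines[starts[s]])),
         positions = pos, loops = loops)
  })
  build_ensemble(snapshots, N, interval)
}

#' Write a dense trajectory as plain text
#'
#' Same dialect as [write_ensemble()] without loop lines, plus an
#' `# every <k>` header giving the frame spacing in MCS.
#'
#' @param trajectory A `dl_trajectory`.
#' @param path Output path.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "dl_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# dynloop trajectory",
               paste("# N", trajectory$N),
               paste("# every", trajectory$every)), con)
  for (k in seq_len(dim(trajectory$positions)[3])) {
    writeLines(paste("# MCS", format(trajectory$mcs[k], scientific = FALSE)), con)
    pos <- trajectory$positions[, , k]
    writeLines(paste(pos[, 1], pos[, 2], pos[, 3]), con)
  }
  invisible(path)
}

#' Read a plain-text dense trajectory
#'
#' @param path File written by [write_trajectory()].
#' @return A `dl_trajectory`.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  lines <- readLines(path)
  n_line <- grep("^# N ", lines, value = TRUE)
  if (length(n_line) == 0) stop("not a dynloop trajectory file")
  N <- as.integer(sub("^# N ", "", n_line[1]))
  ev_line <- grep("^# every ", lines, value = TRUE)
  every <- if (length(ev_line) > 0) as.integer(sub("^# every ", "", ev_line[1])) else 1L
  starts <- grep("^# MCS ", lines)
  frames <- lapply(seq_along(starts), function(s) {
    from <- starts[s] + 1
    to <- if (s < length(starts)) starts[s + 1] - 1 else length(lines)
    body <- lines[from:to]
    body <- body[!grepl("^#", body)]
    matrix(as.integer(unlist(strsplit(body, "[ \t]+"))), ncol = 3, byrow = TRUE)
  })
  mcs <- as.numeric(sub("^# MCS ", "", lines[starts]))
  build_trajectory(frames, mcs, every)
}
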