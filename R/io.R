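#' @include AllClasses.R
NULL

.readLinesChecked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readLines(path, warn = FALSE)
}

.splitFields <- function(lines, nField, path, what) {
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  # strsplit drops a trailing empty field (e.g. an empty fingerprint)
  short <- lengths(parts) == nField - 1L & endsWith(lines[keep], "\t")
  parts[short] <- lapply(parts[short], c, "")
  bad <- which(lengths(parts) != nField)
  if (length(bad))
    stop("malformed ", what, " line ", keep[bad[1L]], " in ", path,
         " (expected ", nField, " tab-separated fields): ",
         lines[keep[bad[1L]]])
  list(parts = parts, lineno = keep)
}

#' Read and write SMILES libraries
#'
#' A `.smi` library has one molecule per line, `SMILES<TAB>id`; lines
#' starting with `#` are comments. SMILES strings are carried as
#' uninterpreted text (only the LINGO fingerprint ever looks inside
#' them).
#'
#' @param path File path.
#' @param molecules For `writeSmiles()`, a data.frame with columns `id`
#'   and `smiles`.
#' @return `readSmiles()` returns a data.frame with character columns
#'   `id` and `smiles`, one row per molecule; ids are checked unique and
#'   SMILES non-empty, with errors naming the offending line.
#' @export
readSmiles <- function(path) {
  lines <- .readLinesChecked(path)
  sp <- .splitFields(lines, 2L, path, ".smi")
  if (!length(sp$parts))
    return(data.frame(id = character(), smiles = character()))
  smiles <- vapply(sp$parts, `[`, character(1), 1L)
  id <- vapply(sp$parts, `[`, character(1), 2L)
  empty <- which(!nzchar(smiles) | !nzchar(id))
  if (length(empty))
    stop("empty SMILES or id on line ", sp$lineno[empty[1L]], " in ", path)
  dupIdx <- which(duplicated(id))
  if (length(dupIdx))
    stop("duplicate molecule id '", id[dupIdx[1L]], "' on line ",
         sp$lineno[dupIdx[1L]], " in ", path)
  data.frame(id = id, smiles = smiles)
}

#' @rdname readSmiles
#' @export
writeSmiles <- function(molecules, path) {
  stopifnot(is.data.frame(molecules), all(c("id", "smiles") %in% names(molecules)))
  writeLines(paste(molecules$smiles, molecules$id, sep = "\t"), path)
  invisible(path)
}

#' Read and write fingerprint TSV files
#'
#' The interchange format for externally computed fingerprints: one
#' fingerprint per line, `id<TAB>length<TAB>features`, where `length` is
#' the folded bit-vector length or `-` for unfolded fingerprints, and
#' `features` is a comma-separated list — integer on-bit positions when
#' folded, sorted feature strings when unfolded. An empty feature field
#' encodes an empty fingerprint.
#'
#' @param path File path.
#' @param fingerprints Named list of [Fingerprint-class] objects (names
#'   are molecule ids).
#' @param source Source tag stamped on fingerprints read from `path`,
#'   default `"external:file"`.
#' @return `readFingerprints()` returns a named list of
#'   [Fingerprint-class]; write-then-read is the identity on the data
#'   model.
#' @export
readFingerprints <- function(path, source = "external:file") {
  lines <- .readLinesChecked(path)
  sp <- .splitFields(lines, 3L, path, "fingerprint")
  out <- list()
  for (i in seq_along(sp$parts)) {
    f <- sp$parts[[i]]
    if (!nzchar(f[1L]))
      stop("empty id on line ", sp$lineno[i], " in ", path)
    if (f[1L] %in% names(out))
      stop("duplicate fingerprint id '", f[1L], "' on line ",
           sp$lineno[i], " in ", path)
    len <- if (f[2L] == "-") NA_integer_ else suppressWarnings(as.integer(f[2L]))
    if (f[2L] != "-" && (is.na(len) || len < 1L))
      stop("bad length field on line ", sp$lineno[i], " in ", path)
    feats <- if (nzchar(f[3L])) strsplit(f[3L], ",", fixed = TRUE)[[1L]]
             else character()
    fp <- tryCatch(Fingerprint(feats, length = len, source = source),
                   error = function(e)
                     stop("invalid fingerprint on line ", sp$lineno[i],
                          " in ", path, ": ", conditionMessage(e)))
    methods::validObject(fp)
    out[[f[1L]]] <- fp
  }
  out
}

#' @rdname readFingerprints
#' @export
writeFingerprints <- function(fingerprints, path) {
  stopifnot(is.list(fingerprints), !is.null(names(fingerprints)),
            all(nzchar(names(fingerprints))))
  lines <- vapply(names(fingerprints), function(id) {
    fp <- fingerprints[[id]]
    len <- if (is.na(fp@length)) "-" else as.character(fp@length)
    paste(id, len, paste(fp@features, collapse = ","), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write benchmark tables
#'
#' A benchmark TSV has one molecule-target assignment per line,
#' `target_id<TAB>molecule_id<TAB>label<TAB>ac50`, label `active` or
#' `decoy`, and `ac50` a positive number or `-` when no potency is
#' recorded (decoys always use `-`). `readBenchmark()` groups rows into
#' one [TargetBenchmark-class] per target.
#'
#' @param path File path.
#' @param benchmarks For `writeBenchmark()`, a list of
#'   [TargetBenchmark-class].
#' @return `readBenchmark()` returns a named list of
#'   [TargetBenchmark-class], in order of first appearance.
#' @export
readBenchmark <- function(path) {
  lines <- .readLinesChecked(path)
  sp <- .splitFields(lines, 4L, path, "benchmark")
  if (!length(sp$parts)) return(list())
  tgt <- vapply(sp$parts, `[`, character(1), 1L)
  mol <- vapply(sp$parts, `[`, character(1), 2L)
  lab <- vapply(sp$parts, `[`, character(1), 3L)
  acf <- vapply(sp$parts, `[`, character(1), 4L)
  badLab <- which(!lab %in% c("active", "decoy"))
  if (length(badLab))
    stop("bad label '", lab[badLab[1L]], "' on line ", sp$lineno[badLab[1L]],
         " in ", path)
  acv <- rep(NA_real_, length(acf))
  hasAc <- acf != "-"
  acv[hasAc] <- suppressWarnings(as.numeric(acf[hasAc]))
  badAc <- which(hasAc & (is.na(acv) | acv <= 0))
  if (length(badAc))
    stop("bad ac50 '", acf[badAc[1L]], "' on line ", sp$lineno[badAc[1L]],
         " in ", path)
  out <- list()
  for (t in unique(tgt)) {
    sel <- tgt == t
    isAct <- sel & lab == "active"
    dup <- duplicated(mol[sel])
    if (any(dup))
      stop("duplicate molecule id '", mol[sel][dup][1L], "' for target '",
           t, "' in ", path)
    out[[t]] <- TargetBenchmark(t, activeIds = mol[isAct],
                                decoyIds = mol[sel & lab == "decoy"],
                                ac50 = acv[isAct])
  }
  out
}

#' @rdname readBenchmark
#' @export
writeBenchmark <- function(benchmarks, path) {
  lines <- unlist(lapply(benchmarks, function(tb) {
    ac <- ifelse(is.na(tb@ac50), "-",
                 format(tb@ac50, scientific = FALSE, trim = TRUE, digits = 15))
    c(paste(tb@targetId, tb@activeIds, "active", ac, sep = "\t"),
      if (length(tb@decoyIds))
        paste(tb@targetId, tb@decoyIds, "decoy", "-", sep = "\t"))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write pair-score tables
#'
#' A pair table holds one similarity evaluation per row:
#' `target_id<TAB>query_id<TAB>candidate_id<TAB>score<TAB>label`. It is
#' the serialized form of the data.frame produced by
#' [computePairScores()].
#'
#' @param path File path.
#' @param pairs A pair-table data.frame.
#' @return `readPairTable()` returns a data.frame with columns
#'   `targetId`, `queryId`, `candidateId`, `score`, `label`.
#' @export
readPairTable <- function(path) {
  lines <- .readLinesChecked(path)
  sp <- .splitFields(lines, 5L, path, "pair-table")
  if (!length(sp$parts))
    return(data.frame(targetId = character(), queryId = character(),
                      candidateId = character(), score = numeric(),
                      label = character()))
  sc <- suppressWarnings(as.numeric(vapply(sp$parts, `[`, character(1), 4L)))
  bad <- which(!is.finite(sc))
  if (length(bad))
    stop("bad score on line ", sp$lineno[bad[1L]], " in ", path)
  data.frame(targetId = vapply(sp$parts, `[`, character(1), 1L),
             queryId = vapply(sp$parts, `[`, character(1), 2L),
             candidateId = vapply(sp$parts, `[`, character(1), 3L),
             score = sc,
             label = vapply(sp$parts, `[`, character(1), 5L))
}

#' @rdname readPairTable
#' @export
writePairTable <- function(pairs, path) {
  writeLines(paste(pairs$targetId, pairs$queryId, pairs$candidateId,
                   format(pairs$score, scientific = FALSE, trim = TRUE,
                          digits = 15),
                   pairs$label, sep = "\t"), path)
  invisible(path)
}

#' Write a benchmark report as JSON
#'
#' Serializes the report list produced by [runBenchmark()] to pretty JSON
#' with stable number formatting, so that identical inputs yield
#' byte-identical files.
#'
#' @param report A report list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path) {
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}
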