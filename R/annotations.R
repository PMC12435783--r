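# Annotation tiers: timestamped, labelled word and phoneme segments, the raw
# material for the onset regressors. Consumed from forced-alignment output as
# TSV or a minimal TextGrid interval dialect.

#' Construct an annotation tier
#'
#' A tier is an ordered table of labelled time intervals, in seconds from
#' trial start, for one linguistic unit (words or phonemes).
#'
#' @param onset,offset Numeric vectors of interval boundaries in seconds.
#' @param label Character vector of segment labels.
#' @param tier_name `"word"` or `"phoneme"`.
#' @return A `data.frame` of class `annotation_tier` with columns
#'   `onset`, `offset`, `label` and attribute `tier_name`.
#' @export
annotation_tier <- function(onset, offset, label = NULL, tier_name = "word") {
  stopifnot(length(onset) == length(offset))
  if (is.null(label)) label <- rep("", length(onset))
  tier <- data.frame(onset = as.numeric(onset), offset = as.numeric(offset),
                     label = as.character(label), stringsAsFactors = FALSE)
  tier <- tier[order(tier$onset), , drop = FALSE]
  rownames(tier) <- NULL
  attr(tier, "tier_name") <- match.arg(tier_name, c("word", "phoneme"))
  class(tier) <- c("annotation_tier", "data.frame")
  tier
}

tier_name <- function(tier) attr(tier, "tier_name")

#' Validate a word/phoneme tier pair
#'
#' Checks that each tier is sorted with positive-length, non-overlapping
#' events and that every phoneme lies within exactly one word interval.
#' Errors name the first offending event.
#'
#' @param word,phoneme `annotation_tier` objects.
#' @param tol Numeric slack in seconds for boundary comparisons.
#' @return Invisibly `TRUE` on success.
#' @export
validate_annotation_tiers <- function(word, phoneme, tol = 1e-9) {
  check_one <- function(tier, what) {
    if (nrow(tier) == 0) stop(sprintf("%s tier is empty", what))
    bad <- which(tier$offset <= tier$onset)
    if (length(bad)) {
      stop(sprintf("%s event %d ('%s') has offset <= onset (%.4f, %.4f)",
                   what, bad[1], tier$label[bad[1]],
                   tier$onset[bad[1]], tier$offset[bad[1]]))
    }
    if (is.unsorted(tier$onset)) {
      stop(sprintf("%s tier onsets are not sorted", what))
    }
    if (nrow(tier) > 1) {
      ov <- which(tier$onset[-1] < tier$offset[-nrow(tier)] - tol)
      if (length(ov)) {
        stop(sprintf("%s events %d and %d overlap (offset %.4f > next onset %.4f)",
                     what, ov[1], ov[1] + 1,
                     tier$offset[ov[1]], tier$onset[ov[1] + 1]))
      }
    }
  }
  check_one(word, "word")
  check_one(phoneme, "phoneme")
  # every phoneme must fall inside exactly one word interval
  hit <- findInterval(phoneme$onset + tol, word$onset)
  inside <- hit >= 1 &
    phoneme$onset >= word$onset[pmax(hit, 1)] - tol &
    phoneme$offset <= word$offset[pmax(hit, 1)] + tol
  if (any(!inside)) {
    b <- which(!inside)[1]
    stop(sprintf(
      "phoneme event %d ('%s', %.4f-%.4f s) lies outside every word interval",
      b, phoneme$label[b], phoneme$onset[b], phoneme$offset[b]))
  }
  invisible(TRUE)
}

#' Read word and phoneme tiers from disk
#'
#' Two dialects are supported: a four-column TSV
#' (`tier`, `onset_s`, `offset_s`, `label`) and a minimal TextGrid subset —
#' a long-format `IntervalTier` file with tiers named `word`/`words` and
#' `phoneme`/`phonemes` (empty labels are treated as silences and dropped).
#' The parsed result is validated against the tier invariants.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"textgrid"`.
#' @return List with elements `word` and `phoneme` (each an `annotation_tier`).
#' @export
read_annotations <- function(path, dialect = c("tsv", "textgrid")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  tiers <- if (dialect == "tsv") read_annotations_tsv(path) else read_textgrid_subset(path)
  validate_annotation_tiers(tiers$word, tiers$phoneme)
  tiers
}

read_annotations_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  need <- c("tier", "onset_s", "offset_s", "label")
  if (!all(need %in% names(tab))) {
    stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
  }
  pick <- function(nm) {
    rows <- tab[tab$tier == nm, , drop = FALSE]
    annotation_tier(rows$onset_s, rows$offset_s, rows$label, nm)
  }
  list(word = pick("word"), phoneme = pick("phoneme"))
}

read_textgrid_subset <- function(path) {
  lines <- readLines(path, warn = FALSE)
  grab <- function(pat, x) {
    m <- regmatches(x, regexpr(pat, x))
    as.numeric(sub(".*= *", "", m))
  }
  tier_starts <- grep("item *\\[[0-9]+\\]", lines)
  if (!length(tier_starts)) stop("no interval tiers found in TextGrid")
  out <- list()
  bounds <- c(tier_starts, length(lines) + 1)
  for (i in seq_along(tier_starts)) {
    chunk <- lines[bounds[i]:(bounds[i + 1] - 1)]
    nm_line <- grep("name *=", chunk, value = TRUE)[1]
    if (is.na(nm_line)) next
    nm <- tolower(gsub('.*name *= *"([^"]*)".*', "\\1", nm_line))
    nm <- sub("s$", "", nm)
    if (!nm %in% c("word", "phoneme")) next
    xmins <- grab("xmin *= *[0-9.eE+-]+", chunk)[-1] # first xmin is the tier's
    xmaxs <- grab("xmax *= *[0-9.eE+-]+", chunk)[-1]
    labs <- gsub('.*text *= *"([^"]*)".*', "\\1",
                 grep("text *=", chunk, value = TRUE))
    keep <- labs != ""
    out[[nm]] <- annotation_tier(xmins[keep], xmaxs[keep], labs[keep], nm)
  }
  if (is.null(out$word) || is.null(out$phoneme)) {
    stop("TextGrid must contain both a word and a phoneme interval tier")
  }
  out
}

#' Write tiers as annotation TSV
#'
#' @param word,phoneme `annotation_tier` objects.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_annotations_tsv <- function(word, phoneme, path) {
  tab <- rbind(
    data.frame(tier = "word", onset_s = word$onset, offset_s = word$offset,
               label = word$label),
    data.frame(tier = "phoneme", onset_s = phoneme$onset,
               offset_s = phoneme$offset, label = phoneme$label))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write tiers in the minimal TextGrid interval dialect
#'
#' Produces a long-format TextGrid with two interval tiers (`word`,
#' `phoneme`); gaps between annotated segments are written as empty-label
#' intervals, as forced aligners do.
#'
#' @inheritParams write_annotations_tsv
#' @export
write_annotations_textgrid <- function(word, phoneme, path) {
  xmax <- max(word$offset, phoneme$offset)
  fill_gaps <- function(tier) {
    segs <- data.frame(onset = tier$onset, offset = tier$offset,
                       label = tier$label)
    out <- list()
    cur <- 0
    for (i in seq_len(nrow(segs))) {
      if (segs$onset[i] > cur + 1e-12) {
        out[[length(out) + 1]] <- data.frame(onset = cur, offset = segs$onset[i],
                                             label = "")
      }
      out[[length(out) + 1]] <- segs[i, ]
      cur <- segs$offset[i]
    }
    if (cur < xmax - 1e-12) {
      out[[length(out) + 1]] <- data.frame(onset = cur, offset = xmax, label = "")
    }
    do.call(rbind, out)
  }
  emit_tier <- function(tier, nm, idx) {
    segs <- fill_gaps(tier)
    c(sprintf("    item [%d]:", idx),
      '        class = "IntervalTier"',
      sprintf('        name = "%s"', nm),
      "        xmin = 0",
      sprintf("        xmax = %.10g", xmax),
      sprintf("        intervals: size = %d", nrow(segs)),
      unlist(lapply(seq_len(nrow(segs)), function(i) {
        c(sprintf("        intervals [%d]:", i),
          sprintf("            xmin = %.10g", segs$onset[i]),
          sprintf("            xmax = %.10g", segs$offset[i]),
          sprintf('            text = "%s"', segs$label[i]))
      })))
  }
  lines <- c('File type = "ooTextFile"', 'Object class = "TextGrid"', "",
             "xmin = 0", sprintf("xmax = %.10g", xmax),
             "tiers? <exists>", "size = 2", "item []:",
             emit_tier(word, "word", 1), emit_tier(phoneme, "phoneme", 2))
  writeLines(lines, path)
  invisible(path)
}

#' Median and quartile durations of words and phonemes
#'
#' @param word,phoneme `annotation_tier` objects (nonempty).
#' @return List with components `word` and `phoneme`, each a named vector
#'   `c(median, q25, q75)` in seconds.
#' @export
stimulus_statistics <- function(word, phoneme) {
  summ <- function(tier, what) {
    if (nrow(tier) == 0) stop(sprintf("%s tier is empty", what))
    d <- tier$offset - tier$onset
    q <- stats::quantile(d, c(0.5, 0.25, 0.75), names = FALSE)
    c(median = q[1], q25 = q[2], q75 = q[3])
  }
  list(word = summ(word, "word"), phoneme = summ(phoneme, "phoneme"))
}
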