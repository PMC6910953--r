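#' Manner-of-articulation classes
#'
#' The six manner classes used for phonemic grouping, plus \code{other}
#' for silence, pauses and unmapped labels.
#'
#' @return Character vector of class names.
#' @export
manner_classes <- function() {
  c("affricate", "fricative", "liquid", "nasal", "plosive", "vowel", "other")
}

#' Default Spanish phone-to-manner mapping
#'
#' Maps a Spanish (IPA-style) phone inventory onto manner classes
#' following the classical Quilis categorization: plosives
#' \code{p t k b d g}; fricatives \code{f θ s ʂ x ʝ β
#' ð ɣ}; the affricate \code{tʃ}; liquids \code{l ʎ
#' ɾ r ř}; nasals \code{m n ɲ ŋ}; vowels
#' \code{a e i o u} plus the glides \code{j w} (which pattern with vowels
#' in diphthongs); silence and pause labels map to \code{other}. The
#' spirantized approximants \code{β ð ɣ} are classed by
#' their surface manner (fricative), not their canonical plosive phoneme;
#' override the table if the opposite convention is wanted.
#'
#' @return A \code{manner_map}: data frame with columns \code{label} and
#'   \code{manner}.
#' @export
default_manner_map <- function() {
  tab <- list(
    plosive   = c("p", "t", "k", "b", "d", "g"),
    fricative = c("f", "\u03b8", "s", "\u0282", "x", "\u029d",
                  "\u03b2", "\u00f0", "\u0263"),
    affricate = c("t\u0283", "ch"),
    liquid    = c("l", "\u028e", "\u027e", "r", "\u0159"),
    nasal     = c("m", "n", "\u0272", "\u014b"),
    vowel     = c("a", "e", "i", "o", "u", "j", "w"),
    other     = c("sil", "sp", "spn", "pau", "")
  )
  mm <- data.frame(
    label = unlist(tab, use.names = FALSE),
    manner = rep(names(tab), lengths(tab)),
    stringsAsFactors = FALSE
  )
  class(mm) <- c("manner_map", "data.frame")
  mm
}

#' Map phone labels to manner classes
#'
#' @param labels Character vector of phone labels.
#' @param manner_map A mapping data frame (\code{label}, \code{manner});
#'   defaults to [default_manner_map()]. Labels absent from the map fall
#'   back to \code{other} with a warning.
#' @return Character vector of manner classes, same length as
#'   \code{labels}.
#' @export
map_manner <- function(labels, manner_map = default_manner_map()) {
  idx <- match(labels, manner_map$label)
  if (anyNA(idx)) {
    missing <- unique(labels[is.na(idx)])
    warning("unmapped phone labels assigned to 'other': ",
            paste(missing, collapse = ", "))
  }
  out <- manner_map$manner[idx]
  out[is.na(out)] <- "other"
  out
}

#' Read a phone alignment file
#'
#' Reads phone-level intervals from a Praat TextGrid (first interval tier,
#' by convention named \code{phones}) or a CTM file
#' (\code{utt channel start dur label} per line), maps labels to manner
#' classes, and returns sorted, non-overlapping segments.
#'
#' @param path Alignment file.
#' @param manner_map Phone-to-manner mapping; see [default_manner_map()].
#' @param format \code{"auto"} (by extension), \code{"textgrid"} or
#'   \code{"ctm"}.
#' @return Data frame with columns \code{label}, \code{start}, \code{end}
#'   (seconds) and \code{manner}, sorted by \code{start}. Empty file gives
#'   zero rows; overlapping intervals are an error.
#' @export
read_alignment <- function(path, manner_map = default_manner_map(),
                           format = c("auto", "textgrid", "ctm")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.textgrid$", path, ignore.case = TRUE))
      "textgrid" else if (grepl("\\.ctm$", path, ignore.case = TRUE))
      "ctm" else stop("cannot infer alignment format from extension: ", path)
  }
  seg <- switch(format,
                textgrid = read_textgrid_intervals(path),
                ctm = read_ctm_intervals(path))
  if (nrow(seg) == 0L) {
    seg$manner <- character(0)
    return(seg)
  }
  seg <- seg[order(seg$start), , drop = FALSE]
  if (any(seg$end[-nrow(seg)] > seg$start[-1L] + 1e-9))
    stop("overlapping intervals in ", path)
  if (any(seg$end <= seg$start)) stop("non-positive interval in ", path)
  seg$manner <- map_manner(seg$label, manner_map)
  rownames(seg) <- NULL
  seg
}

read_textgrid_intervals <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  num_after <- function(l) as.numeric(sub(".*=\\s*", "", l))
  str_after <- function(l) {
    v <- sub('^[^"]*"', "", l)
    sub('"\\s*$', "", v)
  }
  xmin <- grep("^\\s*xmin\\s*=", lines)
  xmax <- grep("^\\s*xmax\\s*=", lines)
  text <- grep("^\\s*text\\s*=", lines)
  # interval entries are the xmin/xmax pairs immediately preceding a text line
  out <- data.frame(label = character(0), start = numeric(0), end = numeric(0),
                    stringsAsFactors = FALSE)
  for (t in text) {
    s <- max(xmin[xmin < t])
    e <- max(xmax[xmax < t])
    out <- rbind(out, data.frame(
      label = str_after(lines[t]),
      start = num_after(lines[s]),
      end = num_after(lines[e]),
      stringsAsFactors = FALSE))
  }
  out
}

read_ctm_intervals <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(label = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- vapply(parts, length, 1L) < 5L
  if (any(bad)) stop("malformed CTM line(s) in ", path)
  start <- vapply(parts, function(p) as.numeric(p[3L]), 1)
  dur <- vapply(parts, function(p) as.numeric(p[4L]), 1)
  data.frame(label = vapply(parts, `[`, "", 5L),
             start = start, end = start + dur, stringsAsFactors = FALSE)
}

#' Select the frames of one manner class
#'
#' A frame belongs to a segment when its center time lies in the
#' half-open interval \code{[start, end)}; this assigns every
#' 50 %-overlapped frame to exactly one phone even at segment boundaries.
#'
#' @param frames A [frame_matrix()].
#' @param segments Alignment segments from [read_alignment()].
#' @param target A manner class name.
#' @return List with \code{frames} (the selected-row [frame_matrix()])
#'   and \code{mask} (logical, length N). An absent class gives an empty
#'   subset.
#' @export
select_frames <- function(frames, segments, target) {
  stopifnot(target %in% manner_classes())
  mask <- rep(FALSE, nrow(frames$values))
  seg <- segments[segments$manner == target, , drop = FALSE]
  for (i in seq_len(nrow(seg))) {
    mask <- mask | (frames$frame_times >= seg$start[i] &
                    frames$frame_times < seg$end[i])
  }
  list(frames = frame_matrix(frames$values[mask, , drop = FALSE],
                             frames$frame_times[mask],
                             frames$utterance_id),
       mask = mask)
}

#' Group a corpus by one manner class
#'
#' Applies [select_frames()] to every utterance of a corpus, retaining
#' speaker and class provenance. Utterances with no frames in the target
#' class are kept with an empty matrix (the scoring stage flags them);
#' utterances lacking an alignment are skipped with a warning.
#'
#' @param corpus A \code{sim_corpus} (see [generate_corpus()]) or any list
#'   of utterance records with fields \code{frames}, \code{segments},
#'   \code{speaker_id}, \code{class}, \code{utterance_id}.
#' @param target Manner class to keep.
#' @return A list of records with the grouped \code{frames}; attribute
#'   \code{n_skipped} counts utterances without alignments.
#' @export
group_corpus <- function(corpus, target) {
  utts <- if (inherits(corpus, "sim_corpus")) corpus$utterances else corpus
  skipped <- 0L
  out <- lapply(utts, function(u) {
    if (is.null(u$segments)) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    sel <- select_frames(u$frames, u$segments, target)
    list(speaker_id = u$speaker_id, class = u$class,
         utterance_id = u$utterance_id, frames = sel$frames,
         mask = sel$mask)
  })
  if (skipped > 0L) warning(skipped, " utterance(s) without alignment skipped")
  out <- out[!vapply(out, is.null, TRUE)]
  attr(out, "n_skipped") <- skipped
  out
}
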