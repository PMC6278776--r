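#' Repeat units recognised in interruption-pattern strings
#'
#' The hexamer CCGCTG is a first-class unit: runs of it occur in some
#' interrupted DMPK expansions and each repeat contributes two
#' trinucleotide units to length arithmetic.
#' @keywords internal
.pattern_units <- c("CCGCTG", "CTG", "CCG", "CTC", "GGC", "CAG")

#' Trinucleotides contributed by one repeat of each unit
#' @keywords internal
.unit_weight <- c(CCGCTG = 2L, CTG = 1L, CCG = 1L, CTC = 1L, GGC = 1L,
                  CAG = 1L)

#' Parse a repeat-interruption pattern string
#'
#' Patterns describe the block structure of an expanded CTG repeat tract,
#' e.g. \code{"(CTG)n CTC (CTG)26"}: a 5' pure CTG tract of unknown length
#' followed by interrupting blocks. Accepted blocks are \code{(UNIT)k},
#' \code{(UNIT)n} (unknown count) or a bare \code{UNIT} (count 1), where
#' UNIT is one of CTG, CCG, CTC, GGC, CAG or the hexamer CCGCTG.
#' Whitespace, underscores and asterisks (as found in formatted tables,
#' e.g. \code{"(CTG)_n_(CCGCTG)_3_"}) are ignored.
#'
#' @param text pattern string.
#' @return An object of class \code{"interruption_pattern"}: a list with
#'   \code{blocks} (data frame with columns \code{unit} and \code{count};
#'   \code{count} is \code{NA} for an unknown "n" block) and
#'   \code{source_text}.
#' @examples
#' p <- parse_interruption_pattern("(CTG)n CTC (CTG)26")
#' p$blocks
#' is_pure_pattern(parse_interruption_pattern("(CTG)n"))
#' @export
parse_interruption_pattern <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("pattern text must be a single string")
  source_text <- text
  txt <- gsub("[*_[:space:]]", "", text)
  if (!nzchar(txt)) stop("empty pattern string")

  units <- character(0)
  counts <- integer(0)
  unit_alt <- paste(.pattern_units, collapse = "|")
  re_paren <- paste0("^\\((", unit_alt, ")\\)([0-9]+|n)")
  re_bare <- paste0("^(", unit_alt, ")")
  while (nzchar(txt)) {
    m <- regexec(re_paren, txt)[[1]]
    if (m[1] != -1L) {
      g <- regmatches(txt, list(m))[[1]]
      units <- c(units, g[2])
      counts <- c(counts, if (g[3] == "n") NA_integer_ else as.integer(g[3]))
      txt <- substring(txt, nchar(g[1]) + 1L)
      next
    }
    m <- regexec(re_bare, txt)[[1]]
    if (m[1] != -1L) {
      g <- regmatches(txt, list(m))[[1]]
      units <- c(units, g[2])
      counts <- c(counts, 1L)
      txt <- substring(txt, nchar(g[1]) + 1L)
      next
    }
    stop("malformed pattern near: '", substr(txt, 1L, 12L), "'")
  }
  if (any(!is.na(counts) & counts < 1L))
    stop("block counts must be positive")
  structure(
    list(blocks = data.frame(unit = units, count = counts,
                             stringsAsFactors = FALSE),
         source_text = source_text),
    class = "interruption_pattern")
}

#' Format an interruption pattern back to canonical text
#'
#' Canonical form writes unknown counts as \code{(UNIT)n}, single repeats
#' of non-leading blocks as a bare unit, and all other blocks as
#' \code{(UNIT)k}. Parsing the canonical text reproduces the same blocks.
#'
#' @param pattern an \code{"interruption_pattern"}.
#' @return A single string.
#' @export
format_interruption_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "interruption_pattern"))
  b <- pattern$blocks
  out <- character(nrow(b))
  for (i in seq_len(nrow(b))) {
    if (is.na(b$count[i])) out[i] <- sprintf("(%s)n", b$unit[i])
    else if (b$count[i] == 1L && i > 1L) out[i] <- b$unit[i]
    else out[i] <- sprintf("(%s)%d", b$unit[i], b$count[i])
  }
  paste(out, collapse = "")
}

#' @export
print.interruption_pattern <- function(x, ...) {
  cat("Interruption pattern:", format_interruption_pattern(x), "\n")
  cat(nrow(x$blocks), "block(s);",
      if (is_pure_pattern(x)) "pure CTG expansion" else "interrupted", "\n")
  invisible(x)
}

#' Is a pattern a pure (uninterrupted) CTG expansion?
#'
#' @param pattern an \code{"interruption_pattern"}.
#' @return \code{TRUE} for a single-block \code{(CTG)n} pattern.
#' @export
is_pure_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "interruption_pattern"))
  b <- pattern$blocks
  nrow(b) == 1L && b$unit[1] == "CTG" && is.na(b$count[1])
}

#' Length of the interrupted 3' part of an expansion, in trinucleotides
#'
#' The interrupted part runs from the first non-CTG block to the 3' end,
#' so pure CTG runs lying between interruptions count toward it; what
#' remains upstream is the pure 5' tract. Hexamer CCGCTG blocks contribute
#' two trinucleotides per repeat. When the deposited per-patient
#' subtraction constant is known it can be supplied as \code{override},
#' which then takes precedence over block arithmetic; an override is
#' required whenever a block inside the interrupted part has unknown
#' count.
#'
#' @param pattern an \code{"interruption_pattern"}.
#' @param override optional known interrupted-part length in repeats.
#' @return Integer number of trinucleotide repeats (0 for a pure pattern).
#' @examples
#' p <- parse_interruption_pattern("(CTG)n CTC (CTG)26")
#' interrupted_block_length(p)  # 27
#' @export
interrupted_block_length <- function(pattern, override = NULL) {
  stopifnot(inherits(pattern, "interruption_pattern"))
  if (!is.null(override) && !is.na(override)) {
    override <- as.integer(override)
    if (override < 0L) stop("override must be non-negative")
    return(override)
  }
  b <- pattern$blocks
  first_int <- which(b$unit != "CTG")[1]
  if (is.na(first_int)) return(0L)  # pure: no interrupted part
  idx <- seq.int(first_int, nrow(b))
  if (anyNA(b$count[idx]))
    stop("pattern has a block of unknown count inside the interrupted ",
         "part; supply a per-patient `override` length")
  sum(b$count[idx] * .unit_weight[b$unit[idx]])
}
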