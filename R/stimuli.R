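#' Parse an arithmetic problem string
#'
#' Converts a problem string such as `"36 - 8"` or `"16 x 6"` into a
#' structured problem record. Both ASCII (`-`, `x`, `*`) and typographic
#' (`−`, `×`) operator glyphs are accepted and normalized to a
#' canonical internal form (`"subtraction"` / `"multiplication"`).
#'
#' The stimulus family consists of positive-operand problems with positive
#' solutions: subtractions always have minuend > subtrahend, so a
#' non-positive subtraction result is rejected as a parse error.
#'
#' @param text Problem string: two positive integers separated by an
#'   operator glyph.
#' @param block Block label, one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @return A one-row data.frame with columns `block`, `operand1`,
#'   `operation`, `operand2`, `solution`.
#' @examples
#' parse_problem("6 - 2", "A")
#' parse_problem("16 × 6", "A")
#' @export
parse_problem <- function(text, block) {
  stopifnot(is.character(text), length(text) == 1L)
  block <- match.arg(as.character(block), c("A", "B", "C", "D"))
  norm <- chartr("−×", "-*", text)
  norm <- gsub("x", "*", norm, fixed = TRUE)
  m <- regmatches(norm, regexec("^\\s*(\\d+)\\s*([-*])\\s*(\\d+)\\s*$", norm))[[1]]
  if (length(m) != 4L)
    stop("malformed problem string: ", sQuote(text), call. = FALSE)
  op1 <- as.integer(m[2L])
  op2 <- as.integer(m[4L])
  operation <- if (m[3L] == "-") "subtraction" else "multiplication"
  if (op1 <= 0L || op2 <= 0L)
    stop("non-positive operand in ", sQuote(text), call. = FALSE)
  solution <- if (operation == "subtraction") op1 - op2 else op1 * op2
  if (operation == "subtraction" && solution <= 0L)
    stop("non-positive subtraction result in ", sQuote(text), call. = FALSE)
  data.frame(block = block, operand1 = op1, operation = operation,
             operand2 = op2, solution = solution,
             stringsAsFactors = FALSE)
}

#' Classify problem size
#'
#' A problem is `"small"` when both operands are at most ten and `"large"`
#' otherwise. Small problems are typically solved by direct fact retrieval,
#' large problems by a multi-step procedure; problem size therefore serves
#' as the objective proxy for expected strategy use.
#'
#' @param problems A data.frame of problems (as returned by
#'   [parse_problem()] or [read_problem_set()]).
#' @return Character vector, `"small"` or `"large"`, one entry per problem.
#' @examples
#' p <- rbind(parse_problem("6 - 2", "A"), parse_problem("36 - 8", "B"))
#' classify_size(p)
#' @export
classify_size <- function(problems) {
  stopifnot(all(c("operand1", "operand2") %in% names(problems)))
  ifelse(problems$operand1 <= 10 & problems$operand2 <= 10, "small", "large")
}

#' Read a stimulus set from TSV
#'
#' Reads a tab-separated problem table with columns `block`, `operand1`,
#' `operation`, `operand2`, computes solutions and size classes, and
#' returns the assembled problem table. The packaged 80-problem set is
#' returned when `path` is omitted.
#'
#' @param path Path to a TSV file. Defaults to the stimulus set shipped
#'   with the package (40 subtractions and 40 multiplications in four
#'   blocks).
#' @return A data.frame with columns `block`, `operand1`, `operation`,
#'   `operand2`, `solution`, `size`.
#' @export
read_problem_set <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "problem_set.tsv", package = "oscarith",
                        mustWork = TRUE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("block", "operand1", "operation", "operand2")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("stimulus file missing column(s): ", paste(miss, collapse = ", "))
  txt <- paste(raw$operand1, raw$operation, raw$operand2)
  out <- do.call(rbind, Map(parse_problem, txt, raw$block))
  rownames(out) <- NULL
  out$size <- classify_size(out)
  out
}

#' Validate the design constraints of a problem set
#'
#' Checks a problem set against the design rules of the 80-problem
#' paradigm: five problems in every block x operation x size cell,
#' no duplicate problems, and the borrowing rule for large subtractions
#' (the subtrahend must exceed the ones digit of the minuend, forcing a
#' borrow and hence a genuinely procedural computation).
#'
#' @param problems A problem data.frame (see [read_problem_set()]).
#' @return A list of class `stimulus_validation` with elements
#'   `n_problems`, `n_unique`, `counts` (block x operation x size table),
#'   `violations` (character vector describing each constraint violation),
#'   and `ok` (TRUE when no violations and all cell counts equal five).
#' @export
validate_problem_set <- function(problems) {
  if (is.null(problems) || nrow(problems) == 0L)
    stop("empty problem set")
  if (!"size" %in% names(problems))
    problems$size <- classify_size(problems)
  key <- paste(problems$operand1, problems$operation, problems$operand2)
  dup <- unique(key[duplicated(key)])
  violations <- character(0)
  if (length(dup))
    violations <- c(violations, paste("duplicate problem:", dup))
  large_sub <- problems$operation == "subtraction" & problems$size == "large"
  if (any(large_sub)) {
    ones <- problems$operand1[large_sub] %% 10
    bad <- problems$operand2[large_sub] <= ones
    if (any(bad)) {
      lbl <- paste0(problems$operand1[large_sub][bad], " - ",
                    problems$operand2[large_sub][bad])
      violations <- c(violations,
                      paste("borrowing rule violated (subtrahend <= ones digit of minuend):", lbl))
    }
  }
  counts <- table(block = problems$block,
                  operation = problems$operation,
                  size = problems$size)
  structure(list(
    n_problems = nrow(problems),
    n_unique = length(unique(key)),
    counts = counts,
    violations = violations,
    ok = length(violations) == 0L && all(counts == 5L)
  ), class = "stimulus_validation")
}

#' @export
print.stimulus_validation <- function(x, ...) {
  cat("Stimulus set validation\n")
  cat("  problems:", x$n_problems, "(", x$n_unique, "unique )\n")
  print(x$counts)
  if (length(x$violations)) {
    cat("  violations:\n")
    for (v in x$violations) cat("   -", v, "\n")
  } else cat("  no constraint violations\n")
  invisible(x)
}
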