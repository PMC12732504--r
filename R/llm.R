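## LLM-judge prompt pipeline for pathway relevance: two prompt templates,
## a pluggable text backend (any function prompt -> reply) and a
## deterministic scripted mock for offline use. The default disease
## context matches the study the templates were designed for (type 2
## diabetes mellitus in Mus musculus).

promptTemplate1 <- paste0(
  "You have an expert perspective in bioinformatics. Is %s highly ",
  "relevant for type 2 diabetes mellitus in Mus musculus? Answer with ",
  "Yes or No. Afterwards, describe shortly your explanation for whether ",
  "the pathway involves type 2 diabetes, providing references for your ",
  "claims.")

promptTemplate2 <- paste0(
  "You have an expert perspective in bioinformatics. Your task is to ",
  "very concisely judge whether a pathway is relevant for type 2 ",
  "diabetes mellitus (T2D) in Mus musculus. When asked whether %s is ",
  "highly relevant for T2D in Mus musculus, these were your answers ",
  "from three distinct runs:\n",
  "Answer 1: %s\n",
  "Answer 2: %s\n",
  "Answer 3: %s\n",
  "Now give your final critical verdict with a Yes or No, and describe ",
  "very concisely your explanation (with a few sentences at most), ",
  "using correct scientific references.")

#' Render the first-stage pathway relevance prompt
#'
#' Byte-stable template with the pathway name substituted exactly once.
#'
#' @param pathway Non-empty pathway name.
#' @return Prompt text.
#' @export
renderPromptStage1 <- function(pathway) {
  if (!is.character(pathway) || length(pathway) != 1 || !nzchar(pathway)) {
    stop("pathway name must be a non-empty string")
  }
  sprintf(promptTemplate1, pathway)
}

#' Render the second-stage verdict prompt
#'
#' Byte-stable template with the pathway name and exactly three
#' first-stage answers substituted in order.
#'
#' @param pathway Non-empty pathway name.
#' @param answers Character vector of exactly three first-stage replies.
#' @return Prompt text.
#' @export
renderPromptStage2 <- function(pathway, answers) {
  if (!is.character(pathway) || length(pathway) != 1 || !nzchar(pathway)) {
    stop("pathway name must be a non-empty string")
  }
  if (length(answers) != 3) stop("exactly three answers are required")
  sprintf(promptTemplate2, pathway, answers[1], answers[2], answers[3])
}

#' Parse a Yes/No verdict from a backend reply
#'
#' The first alphabetic token is matched case-insensitively against
#' yes/no; failing that, a fallback scans for a standalone "Yes" or "No"
#' anywhere in the reply (first occurrence wins); otherwise the verdict
#' is `"undetermined"`.
#'
#' @param text Backend reply.
#' @return `"Yes"`, `"No"`, or `"undetermined"`.
#' @export
parseVerdict <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text)) {
    return("undetermined")
  }
  m <- regmatches(text, regexpr("[A-Za-z]+", text))
  if (length(m)) {
    tok <- tolower(m)
    if (tok == "yes") return("Yes")
    if (tok == "no") return("No")
  }
  hit <- regmatches(text, regexpr("\\b([Yy][Ee][Ss]|[Nn][Oo])\\b", text))
  if (length(hit)) {
    return(if (tolower(hit) == "yes") "Yes" else "No")
  }
  "undetermined"
}

#' Deterministic scripted mock backend
#'
#' Returns a backend function (prompt -> reply). `replies` may be a
#' single string (always returned), a character vector (cycled through
#' call by call), or a function of the prompt.
#'
#' @param replies Scripted replies.
#' @return A function of one argument (the prompt) returning text.
#' @export
mockLLMBackend <- function(replies = "Yes. Mock rationale.") {
  if (is.function(replies)) return(replies)
  i <- 0L
  function(prompt) {
    i <<- i + 1L
    replies[((i - 1L) %% length(replies)) + 1L]
  }
}

#' Judge pathway relevance through the two-stage prompt pipeline
#'
#' For each pathway the first-stage prompt is sent three times, the three
#' replies are fed into the second-stage prompt, and the final verdict is
#' parsed from the second-stage reply. Backend failures are retried up to
#' three times per call; a pathway whose calls keep failing is marked
#' `"undetermined"`. All raw prompts and replies are retained for audit.
#'
#' @param pathways Character vector of pathway names.
#' @param backend Backend function (prompt -> reply text), e.g.
#'   [mockLLMBackend()] or a wrapper around a live API.
#' @return data.frame with columns `pathway`, `verdict`, `explanation`,
#'   plus a list-column `answers` holding the three first-stage replies;
#'   full transcripts in `attr(, "transcripts")`.
#' @export
judgePathways <- function(pathways, backend) {
  callBackend <- function(prompt) {
    for (attempt in 1:3) {
      res <- tryCatch(backend(prompt), error = function(e) e)
      if (!inherits(res, "error")) return(res)
    }
    NA_character_
  }
  rows <- vector("list", length(pathways))
  transcripts <- vector("list", length(pathways))
  for (i in seq_along(pathways)) {
    pw <- pathways[i]
    p1 <- renderPromptStage1(pw)
    answers <- vapply(1:3, function(k) callBackend(p1), character(1))
    if (anyNA(answers)) {
      rows[[i]] <- data.frame(pathway = pw, verdict = "undetermined",
                              explanation = NA_character_,
                              stringsAsFactors = FALSE)
      transcripts[[i]] <- list(stage1 = p1, answers = answers,
                               stage2 = NA, final = NA)
      next
    }
    p2 <- renderPromptStage2(pw, answers)
    final <- callBackend(p2)
    verdict <- if (is.na(final)) "undetermined" else parseVerdict(final)
    rows[[i]] <- data.frame(pathway = pw, verdict = verdict,
                            explanation = if (is.na(final)) NA_character_
                                          else final,
                            stringsAsFactors = FALSE)
    transcripts[[i]] <- list(stage1 = p1, answers = answers, stage2 = p2,
                             final = final)
  }
  out <- do.call(rbind, rows)
  out$answers <- lapply(transcripts, `[[`, "answers")
  attr(out, "transcripts") <- transcripts
  out
}

#' Write judge results as JSON lines
#'
#' One JSON object per pathway with the raw prompts and replies, for
#' audit.
#'
#' @param judged Output of [judgePathways()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeVerdictLog <- function(judged, path) {
  transcripts <- attr(judged, "transcripts")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(judged))) {
    rec <- list(pathway = judged$pathway[i], verdict = judged$verdict[i],
                transcript = transcripts[[i]])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null",
                                na = "null"), con)
  }
  invisible(path)
}
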