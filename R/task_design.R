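# Trial-sequence construction for the three inhibition paradigms.
#
# All three builders return a `task_design`: a data frame with one row per
# trial and the full timing/stimulus description needed to simulate the
# session and to epoch the EEG afterwards. "Equal probability" of stimulus
# combinations is implemented as exact balanced counts per block with a
# seeded shuffle, so every design invariant is deterministic and checkable.

STROOP_COLORS   <- c("red", "green", "yellow", "blue")
NP_VOWELS       <- c("A", "E", "O", "U")
NP_CONSONANTS   <- c("H", "K", "N", "R")
FLANKER_STIMULI <- c(compatible1 = "<<<<<", compatible2 = ">>>>>",
                     incompatible1 = ">><>>", incompatible2 = "<<><<")

# condition labels, in (neutral, inhibition) order
task_conditions <- function(task) {
  switch(task,
         stroop  = c("congruent", "incongruent"),
         np      = c("control", "np"),
         flanker = c("compatible", "incompatible"),
         stopf("unknown task '%s'", task))
}

task_buttons <- function(task) {
  switch(task,
         stroop  = STROOP_COLORS,
         np      = c("vowel", "consonant"),
         flanker = c("left", "right"))
}

design_columns <- c("task", "block_index", "block_condition", "trial_index",
                    "condition", "word", "color", "target", "distractor",
                    "stimulus", "correct_response", "fixation_duration",
                    "stimulus_duration", "response_window", "iti_post")

new_task_design <- function(df, task, seed, start_block) {
  df <- df[, design_columns]
  rownames(df) <- NULL
  df$block_index <- as.integer(df$block_index)
  df$trial_index <- as.integer(df$trial_index)
  for (col in c("fixation_duration", "stimulus_duration", "response_window",
                "iti_post"))
    df[[col]] <- as.numeric(df[[col]])
  structure(df, class = c("task_design", "data.frame"),
            task = task, seed = as.integer(seed), start_block = start_block)
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf("<task_design: %s, %d blocks x %d trials, seed %d, start '%s'>\n",
              attr(x, "task"), length(unique(x$block_index)),
              sum(x$block_index == 0), attr(x, "seed"), attr(x, "start_block")))
  invisible(x)
}

block_skeleton <- function(task, block, condition, n) {
  data.frame(task = task, block_index = block, block_condition = condition,
             trial_index = seq_len(n) - 1L, condition = condition,
             word = NA_character_, color = NA_character_,
             target = NA_character_, distractor = NA_character_,
             stimulus = NA_character_, correct_response = NA_character_,
             fixation_duration = NA_real_, stimulus_duration = NA_real_,
             response_window = NA_real_, iti_post = 0,
             stringsAsFactors = FALSE)
}

#' Build a Stroop task design
#'
#' Eight blocks of 36 trials alternating between a fully congruent and a
#' fully incongruent block, starting with `start_block`. Within a congruent
#' block each of the 4 matching word/color pairs appears exactly 9 times;
#' within an incongruent block each of the 12 mismatching pairs appears
#' exactly 3 times; trial order is shuffled under `seed`. The response is the
#' button of the display color. Fixation crosses last 1.0-1.5 s (uniform,
#' quantized to 1 ms) and stimuli stay up for at most 3 s.
#'
#' @param seed Integer seed; designs are reproducible from `(seed, start_block)`.
#' @param start_block Condition of block 0, `"congruent"` or `"incongruent"`.
#'   The study generator alternates this between the pre and post session.
#' @return A `task_design` data frame (288 rows).
#' @export
#' @examples
#' d <- build_stroop_design(1, "congruent")
#' table(d$block_condition[d$trial_index == 0])
build_stroop_design <- function(seed, start_block = c("congruent", "incongruent")) {
  start_block <- match.arg(start_block)
  conds <- c(start_block, setdiff(task_conditions("stroop"), start_block))
  congruent_pairs <- data.frame(word = STROOP_COLORS, color = STROOP_COLORS,
                                stringsAsFactors = FALSE)
  incong <- expand.grid(word = STROOP_COLORS, color = STROOP_COLORS,
                        stringsAsFactors = FALSE)
  incong <- incong[incong$word != incong$color, ]
  blocks <- with_seed(seed, lapply(0:7, function(b) {
    cond <- conds[b %% 2 + 1]
    pairs <- if (cond == "congruent") {
      congruent_pairs[rep(seq_len(4), each = 9), ]
    } else {
      incong[rep(seq_len(12), each = 3), ]
    }
    pairs <- pairs[sample.int(36), ]
    df <- block_skeleton("stroop", b, cond, 36)
    df$word <- pairs$word
    df$color <- pairs$color
    df$correct_response <- pairs$color
    df$fixation_duration <- round(stats::runif(36, 1.0, 1.5), 3)
    df$response_window <- 3
    df
  }))
  new_task_design(do.call(rbind, blocks), "stroop", seed, start_block)
}

# one negative-priming block: in priming blocks the ignored (green) letter of
# trial n becomes the attended (red) letter of trial n + 1; control blocks
# additionally forbid any such carry-over so they contain zero priming.
np_block <- function(block, condition, n = 56) {
  df <- block_skeleton("np", block, condition, n)
  letters_of <- function(class) if (class == "vowel") NP_VOWELS else NP_CONSONANTS
  other <- function(class) if (class == "vowel") "consonant" else "vowel"
  tgt <- character(n); dst <- character(n); tgt_class <- character(n)
  tgt_class[1] <- sample(c("vowel", "consonant"), 1)
  tgt[1] <- sample(letters_of(tgt_class[1]), 1)
  dst[1] <- sample(letters_of(other(tgt_class[1])), 1)
  for (i in 2:n) {
    if (condition == "np") {
      tgt[i] <- dst[i - 1]
      tgt_class[i] <- other(tgt_class[i - 1])
    } else {
      repeat {
        tgt_class[i] <- sample(c("vowel", "consonant"), 1)
        tgt[i] <- sample(letters_of(tgt_class[i]), 1)
        if (tgt[i] != tgt[i - 1] && tgt[i] != dst[i - 1]) break
      }
    }
    dst[i] <- sample(letters_of(other(tgt_class[i])), 1)
  }
  df$target <- tgt
  df$distractor <- dst
  df$correct_response <- ifelse(tgt %in% NP_VOWELS, "vowel", "consonant")
  df$fixation_duration <- round(stats::runif(n, 0.3, 0.5), 3)
  df$stimulus_duration <- 0.5
  df$iti_post <- round(stats::runif(n, 2.3, 2.5), 3)
  df$response_window <- df$stimulus_duration + df$iti_post
  df
}

#' Build a negative-priming task design
#'
#' Four blocks of 56 trials alternating between priming (`"np"`) and
#' `"control"` blocks starting with `start_block`. Each trial overlays one
#' red target letter and one green distractor letter, always one vowel
#' (A, E, O, U) and one consonant (H, K, N, R); the response classifies the
#' red letter as vowel or consonant. In priming blocks the distractor of
#' trial n is the target of trial n + 1; in control blocks the target never
#' matches either letter of the previous trial. Stimuli show for 500 ms
#' followed by a 2.3-2.5 s blank response window; fixation lasts 0.3-0.5 s.
#'
#' @inheritParams build_stroop_design
#' @param start_block Condition of block 0, `"np"` or `"control"`.
#' @return A `task_design` data frame (224 rows).
#' @export
build_negative_priming_design <- function(seed, start_block = c("np", "control")) {
  start_block <- match.arg(start_block)
  conds <- c(start_block, setdiff(task_conditions("np"), start_block))
  blocks <- with_seed(seed, lapply(0:3, function(b) np_block(b, conds[b %% 2 + 1])))
  new_task_design(do.call(rbind, blocks), "np", seed, start_block)
}

#' Build a flanker task design
#'
#' Four blocks of 72 trials with the two conditions mixed within each block:
#' each of the four arrow strings (`<<<<<`, `>>>>>`, `>><>>`, `<<><<`)
#' appears exactly 18 times per block in seeded random order, so compatible
#' and incompatible trials are exactly balanced (36/36). The response is the
#' direction of the central arrow only. Fixation 1.0-1.5 s; response window 3 s.
#'
#' @inheritParams build_stroop_design
#' @return A `task_design` data frame (288 rows).
#' @export
build_flanker_design <- function(seed) {
  blocks <- with_seed(seed, lapply(0:3, function(b) {
    stim <- rep(unname(FLANKER_STIMULI), each = 18)
    stim <- stim[sample.int(72)]
    df <- block_skeleton("flanker", b, "mixed", 72)
    df$stimulus <- stim
    df$condition <- ifelse(stim %in% FLANKER_STIMULI[c("compatible1", "compatible2")],
                           "compatible", "incompatible")
    df$correct_response <- ifelse(substr(stim, 3, 3) == "<", "left", "right")
    df$fixation_duration <- round(stats::runif(72, 1.0, 1.5), 3)
    df$response_window <- 3
    df
  }))
  new_task_design(do.call(rbind, blocks), "flanker", seed, "mixed")
}

#' Build a task design by name
#'
#' @param task One of `"stroop"`, `"np"`, `"flanker"`.
#' @param seed Integer seed.
#' @param start_index 1 or 2: which of the task's two block conditions leads
#'   (ignored for the flanker task, whose blocks are mixed).
#' @return A `task_design`.
#' @export
build_design <- function(task, seed, start_index = 1) {
  task <- match.arg(task, TASKS)
  switch(task,
         stroop  = build_stroop_design(seed, task_conditions("stroop")[start_index]),
         np      = build_negative_priming_design(seed, task_conditions("np")[start_index]),
         flanker = build_flanker_design(seed))
}

#' Write / read a task design as a delimited trial table
#'
#' One row per trial; task, seed and starting block are kept on a `#` header
#' line so the round-trip is lossless.
#'
#' @param design A `task_design`.
#' @param path CSV file path.
#' @return `write_design` returns `path` invisibly; `read_design` returns the
#'   `task_design`.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "task_design"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# task=%s seed=%d start_block=%s", attr(design, "task"),
                     attr(design, "seed"), attr(design, "start_block")), con)
  utils::write.csv(as.data.frame(design), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  header <- readLines(path, n = 1)
  if (!startsWith(header, "# task=")) stopf("'%s' is not a design table", path)
  kv <- strsplit(sub("^# ", "", header), " ")[[1]]
  meta <- stats::setNames(sub("^[^=]+=", "", kv), sub("=.*$", "", kv))
  df <- utils::read.csv(path, skip = 1, stringsAsFactors = FALSE,
                        colClasses = c(task = "character", word = "character",
                                       color = "character", target = "character",
                                       distractor = "character",
                                       stimulus = "character",
                                       correct_response = "character"))
  new_task_design(df, meta[["task"]], as.integer(meta[["seed"]]), meta[["start_block"]])
}
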