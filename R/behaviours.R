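#' Registry of carer communication behaviour codes
#'
#' The default coding scheme for carer (care staff) communication behaviours
#' in dyadic conversations with people with dementia: 22 facilitative and 13
#' non-facilitative codes. Codes appear in transcripts as bracketed labels
#' attached to the turn in which the behaviour occurred, e.g. `[ActListen]`.
#' Labels are fixed identifiers and are matched case-sensitively.
#'
#' @return A data frame with columns `label`, `category`
#'   (`"facilitative"` or `"non_facilitative"`) and `description`.
#' @examples
#' reg <- behaviour_registry()
#' table(reg$category)
#' @export
behaviour_registry <- function() {
  fac <- c(
    VblAck       = "Verbal acknowledgment: backchannel affirming the partner's utterance",
    ActListen    = "Active listening: restate, paraphrase or build on partner content",
    GiveTime     = "Give time: pause to let the partner respond or continue",
    PWDKnowl     = "Use prior knowledge of the partner's life and interests",
    VblEncCont   = "Verbal encouragement to continue (non-affirming continuer)",
    Expand       = "Expand: extra explanation, clues or clarification",
    AnsCont      = "Answer content: offer answer options or examples within a question",
    UseName      = "Address the partner by name",
    SelfDisc     = "Self disclosure: share own circumstances or experiences",
    Rephrase     = "Rephrase own utterance after trouble, with different wording",
    WorkOut      = "Try to work out the partner's intended message",
    Humour       = "Humorous content",
    PWDTopic     = "Take up a topic initiated by the partner",
    ReduceQ      = "Reduce a failed open question to a yes/no or alternative question",
    VisTopic     = "Topic supported by a visual cue in the setting",
    RephQ        = "Immediately rephrase a question without changing the information sought",
    SugCont      = "Suggest content to help word finding or complete an utterance",
    MixedQ       = "Yes/no or alternatives question appended immediately to an open question",
    ManDis       = "Manage distress or upsetting topics sensitively",
    ManConf      = "Manage confusion or memory problems by reassuring, not contradicting",
    AttOrient    = "Explicitly orient the partner's attention",
    ReduceChoice = "Reduce an alternatives question to a single yes/no choice"
  )
  nonfac <- c(
    NoTime       = "Insufficient time left for the partner to respond",
    NoActListen  = "Partner meaning ignored, disregarded or overridden",
    NoManConf    = "Contradict or echo a memory problem instead of reassuring",
    NoClearRef   = "Referent of a pronoun or deictic expression left unclear",
    MultQ        = "Multiple questions for different information with no time between",
    NoRep        = "No repeat or rephrase offered after trouble",
    NoClearTopic = "Topic not made clear when introduced or changed",
    RemQ         = "Follow-up 'do you remember/recall/know' question",
    NoWorkOut    = "No attempt to work out what the partner is trying to say",
    SelfRep      = "Verbatim self-repetition with no pause or trouble in between",
    TestQ        = "Asking for information already known, to probe memory",
    TalkDown     = "Condescending speech (babytalk, elderspeak)",
    NoFamWord    = "Use of a low-frequency or difficult word"
  )
  data.frame(
    label = c(names(fac), names(nonfac)),
    category = rep(c("facilitative", "non_facilitative"), c(length(fac), length(nonfac))),
    description = unname(c(fac, nonfac)),
    stringsAsFactors = FALSE
  )
}

#' Default vocabulary of transcription notations
#'
#' Parenthetical notations recognised in raw transcript text, covering pauses
#' of increasing length, non-verbal events and excluded interruption rows.
#' The vocabulary is configurable because transcription conventions differ
#' between corpora; unknown parentheticals are stripped from the spoken text
#' but not recorded.
#'
#' @return Character vector of notation identifiers.
#' @export
default_notations <- function() {
  c("SPause", "MPause", "LPause", "XLPause",
    "laugh", "laughs", "affirm", "unintelligible", "interruption")
}
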