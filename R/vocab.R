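#' Coding taxonomies for the serious-injury registry
#'
#' The registry codes every case on closed categorical vocabularies:
#' player group (age by years of rugby experience), injury category within
#' a body system (head or spine), cause-of-play, and collision site.
#' Unknown tokens are rejected at parse time.
#'
#' @section Group codes:
#' High-school players are grouped by age and experience. A player is
#' *inexperienced* when the years of experience do not exceed the years
#' since entering high school (age minus 15): codes `16E1`, `17E2`, `18E3`.
#' Players with more experience are coded `16EM`, `17EM`, `18EM`
#' ("many years"). The aggregate codes `16all`, `17all`, `18all` label
#' whole age columns of published tables and never appear on an
#' individual record.
#'
#' @return A data frame describing the vocabulary (one row per code).
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
group_codes <- function() {
  data.frame(
    label = c("16E1", "17E2", "18E3", "16EM", "17EM", "18EM",
              "16all", "17all", "18all"),
    age = rep(c(16L, 17L, 18L), 3L),
    experience_class = rep(c("inexperienced", "many_years", "all"), each = 3L),
    stringsAsFactors = FALSE
  )
}

#' @rdname vocabularies
#' @param body_system `"head"` or `"spine"`.
#' @export
injury_codes <- function(body_system = c("head", "spine")) {
  body_system <- match.arg(body_system)
  if (body_system == "head") {
    data.frame(
      body_system = "head",
      category = c("ASH", "FR", "AEH", "ICH/CC", "CI/CA", "O"),
      description = c("acute subdural hematoma", "fracture",
                      "acute epidural hematoma",
                      "intracerebral hemorrhage / cerebral contusion",
                      "cerebral infarction / cerebrovascular accident",
                      "others or not clear"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      body_system = "spine",
      category = c("VF", "DS", "FD", "CC", "S", "CSC", "O"),
      description = c("vertebral fracture", "dislocation of spine",
                      "fracture dislocation", "central cord", "spinal cord",
                      "cervical spinal cord", "others or not clear"),
      stringsAsFactors = FALSE
    )
  }
}

#' @rdname vocabularies
#' @export
cause_codes <- function() {
  data.frame(
    token = c("T", "OT", "R", "M", "C", "SV", "SC", "O"),
    description = c("own tackle", "oppose tackle",
                    "ruck (one-on-one situation)",
                    "maul (3 or more players battling the ball)",
                    "collision not categorized as above",
                    "saving (hold the ball on the ground)",
                    "scrum (8 players battling the ball)",
                    "other or unknown"),
    # token used when the cause is printed in a registry table
    display = c("T", "OT", "R", "M", "C", "S", "SC", "O"),
    stringsAsFactors = FALSE
  )
}

#' @rdname vocabularies
#' @export
site_codes <- function() {
  data.frame(
    token = c("H-G", "H-H", "H-L", "H-B", "LH", "N-B", "MW", "O"),
    description = c("head to ground", "head to head", "head to leg",
                    "head to other part of opponent's body",
                    "low head (head under the opponent's body)",
                    "neck to other part of opponent's body",
                    "multiple players' weights", "others"),
    stringsAsFactors = FALSE
  )
}

outcome_levels <- function() c("recovered", "sequelae", "death", "unknown")

#' Assign the age-by-experience group code
#'
#' Codes a high-school player as inexperienced (`16E1`, `17E2`, `18E3`)
#' when `experience_years <= age - 15`, i.e. the player cannot have
#' started before entering high school; otherwise as `16EM`/`17EM`/`18EM`
#' (many years of experience). Aggregate `*all` codes are never returned.
#'
#' @param age Integer age in years; must be 16, 17 or 18 (junior records
#'   are tabulated separately and are never group-coded).
#' @param experience_years Integer years of rugby experience, >= 1.
#' @return Character vector of group labels.
#' @examples
#' assign_group_code(16, 1) # "16E1"
#' assign_group_code(17, 2) # "17E2"
#' assign_group_code(16, 8) # "16EM"
#' @export
assign_group_code <- function(age, experience_years) {
  age <- as.integer(age)
  experience_years <- as.integer(experience_years)
  if (length(age) != length(experience_years)) {
    stop("`age` and `experience_years` must have equal length")
  }
  if (any(is.na(age)) || any(!age %in% 16:18)) {
    stop("`age` must be 16, 17 or 18: high-school players only")
  }
  if (any(is.na(experience_years)) || any(experience_years < 1L)) {
    stop("`experience_years` must be an integer >= 1")
  }
  inexperienced <- experience_years <= (age - 15L)
  ifelse(inexperienced,
         paste0(age, "E", age - 15L),
         paste0(age, "EM"))
}
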