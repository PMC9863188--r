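# Survey and service-record recoding.

test_that("combine_any_symptom applies the worst-response priority rule", {
  cases <- list(
    list(c("never", "never"), "never"),
    list(c("never", "often"), "often"),
    list(c("rarely", "sometimes"), "sometimes"),
    list(c("rarely", "never", NA), "rarely"),
    list(c("sometimes", "often", "never"), "often"),
    list(c("rarely", "rarely"), "rarely"),
    list(c(NA, NA), NA_character_),
    list(c(NA, "sometimes", NA), "sometimes")
  )
  for (cs in cases) {
    got <- do.call(combine_any_symptom, as.list(cs[[1]]))
    expect_identical(got, cs[[2]], label = paste(cs[[1]], collapse = "+"))
  }
})

test_that("combine_any_symptom is order-invariant and validates input", {
  set.seed(42)
  pool <- c("never", "rarely", "sometimes", "often", NA)
  for (rep in 1:30) {
    trio <- sample(pool, 3, replace = TRUE)
    base <- combine_any_symptom(trio[1], trio[2], trio[3])
    perm <- sample(3)
    expect_identical(combine_any_symptom(trio[perm[1]], trio[perm[2]], trio[perm[3]]),
                     base)
  }
  expect_error(combine_any_symptom(character(0), character(0)), "empty")
  expect_error(combine_any_symptom("never"), "2 or 3")
  expect_error(combine_any_symptom("never", "a", "never", "never"), "2 or 3")
  expect_error(combine_any_symptom("never", "frequently"), "invalid")
})

test_that("collapse_to_three merges never/rarely and is monotone", {
  expect_identical(collapse_to_three(c("never", "rarely", "sometimes", "often")),
                   c(0L, 0L, 1L, 2L))
  expect_identical(collapse_to_three(NA_character_), NA_integer_)
  expect_error(collapse_to_three("maybe"), "invalid")
  # surjective onto 0..2 and monotone in the response ordering
  codes <- collapse_to_three(c("never", "rarely", "sometimes", "often"))
  expect_setequal(codes, 0:2)
  expect_true(all(diff(codes) >= 0))
})

test_that("recode_symptoms builds the 16-indicator matrix with combination and drop rules", {
  sv <- flat_survey(4)
  # participant 2: urinary pair missing -> any_urinary missing, 15 observed
  sv$urine_burns[2] <- NA
  sv$urine_leak[2] <- NA
  # participant 3: bowel trio escalates to often
  sv$constipation[3] <- "rarely"
  sv$other_bowel[3] <- "often"
  # participant 4: everything missing -> dropped
  for (it in symptom_items()) sv[[it]][4] <- NA

  expect_message(ind <- recode_symptoms(sv), "dropped 1")
  expect_identical(nrow(ind), 3L)
  expect_identical(attr(ind, "n_dropped"), 1L)
  expect_named(ind, c("participant_id", indicator_names()))
  expect_true(all(unlist(ind[1, indicator_names()]) == 0L))
  expect_identical(ind$any_urinary[2], NA_integer_)
  expect_identical(sum(is.na(ind[2, indicator_names()])), 1L)
  expect_identical(ind$any_bowel[3], 2L)
})

test_that("recode_symptoms accepts the integer-code dialect", {
  sv <- flat_survey(2)
  for (it in symptom_items()) sv[[it]] <- c(0L, 3L)
  ind <- recode_symptoms(sv, dialect = "codes")
  expect_true(all(unlist(ind[1, indicator_names()]) == 0L))
  expect_true(all(unlist(ind[2, indicator_names()]) == 2L))
  sv$allergies <- c(5L, 0L)
  expect_error(recode_symptoms(sv, dialect = "codes"), "0..3")
})

test_that("visit bins match the published category boundaries and are exhaustive", {
  expect_equal(as.character(bin_gp_visits(c(0, 1, 2, 3, 4, 6, 7, 9, 10, 12, 13, 40))),
               c("<2", "<2", "2-3", "2-3", "4-6", "4-6", "7-9", "7-9",
                 "10-12", "10-12", ">12", ">12"))
  expect_equal(as.character(bin_specialist_visits(c(0, 1, 2, 3, 11))),
               c("0", "1-2", "1-2", "3+", "3+"))
  expect_equal(as.character(bin_medications(c(0, 1, 2, 3, 9))),
               c("0", "1", "2", "3+", "3+"))
  for (f in list(bin_gp_visits, bin_specialist_visits, bin_medications)) {
    expect_false(anyNA(f(0:50)))   # every non-negative count lands in a bin
    expect_error(f(-1), "non-negative")
  }
})

test_that("service-use recoding applies the 12-month and Apr-Sep windows", {
  sd <- tibble::tibble(participant_id = c("A", "B"),
                       return_date = as.Date("2017-05-01"))
  # A: 3 GP visits but one beyond the window end -> "2-3"
  visits <- tibble::tibble(
    participant_id = c("A", "A", "A", "B"),
    provider_type = c("gp", "gp", "gp", "specialist"),
    date = as.Date(c("2017-05-01", "2018-04-30", "2018-05-01", "2017-06-01")))
  # A: duplicate ATC dispensings count once; October dispensing excluded
  disp <- tibble::tibble(
    participant_id = c("A", "A", "A", "B"),
    atc_code = c("A01AA01", "A01AA01", "N02BE01", "C03CA01"),
    date = as.Date(c("2017-05-10", "2017-06-10", "2017-08-01", "2017-10-01")))
  out <- recode_service_use(sd, visits = visits, dispensings = disp)
  expect_equal(as.character(out$gp_category), c("2-3", "<2"))
  expect_equal(as.character(out$specialist_category), c("0", "1-2"))
  expect_equal(as.character(out$medication_category), c("2", "0"))
  expect_error(recode_service_use(sd, dispensings = tibble::tibble(
    participant_id = "A", atc_code = "BAD", date = as.Date("2017-05-01"))),
    "malformed ATC")
})

test_that("admission flags exclude pregnancy-coded and out-of-window admissions", {
  sd <- tibble::tibble(participant_id = c("A", "B", "C", "D"),
                       return_date = as.Date("2017-05-01"))
  adm <- tibble::tibble(
    participant_id = c("A", "B", "C", "C"),
    admission_date = as.Date(c("2017-08-01", "2017-08-01", "2017-08-01", "2018-06-01")),
    same_day = c(FALSE, TRUE, FALSE, TRUE),
    primary_icd10 = c("O80", "K35", "O9A", "K35"))
  out <- recode_service_use(sd, admissions = adm)
  expect_equal(out$any_admission, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(out$same_day_admission, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(out$overnight_admission, c(FALSE, FALSE, FALSE, FALSE))
})

test_that("ICD-10 pregnancy range uses digit-before-letter ordering in position 3", {
  expect_true(all(icd10_is_pregnancy(c("O00", "O03", "O80", "O99", "O9A", "O26.1"))))
  expect_false(any(icd10_is_pregnancy(c("O9B", "K35", "N39", "A00", "Z99"))))
  expect_error(icd10_is_pregnancy("8X!"), "unparseable")
})
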