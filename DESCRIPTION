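Package: dhitext
Title: Text Analytics for Digital Health Interventions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns the free-text trace of a digital health intervention
    (diary and exercise snippets, coach-user messages) into fixed-length
    numeric feature vectors, aligns them in time with symptom reports, and
    fits two model families: snippet-level symptom inference with within-
    and across-user evaluation, and user-level outcome prediction with
    L1-penalized feature selection. Feature families cover metadata, word
    usage with document-frequency filtering, word-embedding averages, Penn
    Treebank part-of-speech counts, latent Dirichlet allocation topic
    proportions, and sentiment lexicon scores (NRC, AFINN, Bing dialects).
    Includes a synthetic journey generator with planted text-symptom
    coupling for end-to-end validation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    ranger,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
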