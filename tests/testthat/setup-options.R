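# keep the full suite running even when several acceptance checks fail
options(testthat.progress.max_fails = 1000)
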