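# External data drop-in

The package ships no measured Cq data. To verify the published mixture
summaries against the original interlaboratory study, place its
supplementary Cq tables here as:

* `additional_file_3.csv` — RNA mixture Cq values
* `additional_file_4.csv` — cell line mixture Cq values

Files may use the canonical schema (see `?cq_columns`) or arbitrary
headers accompanied by a `dialect_3.yaml` / `dialect_4.yaml` mapping
(canonical name -> file header, see `?read_cq_table`). The acceptance
test `tests/testthat/test-acceptance.R` then checks the published
per-isolation (miR-21, BDL) and per-plate (miR-126, BRL) mean dCq values.
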