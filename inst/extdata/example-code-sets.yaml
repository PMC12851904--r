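# Simplified synthetic stand-in for the full cause-of-death code lists:
# outcome name -> codes counted for that outcome. Read with read_code_sets().
dementia:
  - F00
  - F01
  - F02
  - F03
  - G30
  - G31.8
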