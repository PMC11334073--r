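family	label
og1	nonviral_specific
og2	viral_specific
og3	viral_specific
ogm	viral_specific
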