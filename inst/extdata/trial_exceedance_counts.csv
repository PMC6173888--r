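group,expected_days,actual_days,days_exceeding
observation,328,245,207
feedback,175,176,115
no_feedback,152,159,87
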