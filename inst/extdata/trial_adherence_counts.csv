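group,total_days,weekdays,recorded_days,days_4,days_3,days_2,days_1
observation,450,328,245,49,145,34,17
feedback,240,175,176,131,38,6,1
no_feedback,216,152,159,131,23,4,1
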