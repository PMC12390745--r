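evidence,benefit,economics,recommendation
VERY_LOW_NULL,MARGINAL_NULL_UNCERTAIN_NEGATIVE,UNFAVORABLE,STRONGLY_AGAINST
VERY_LOW_NULL,MARGINAL_NULL_UNCERTAIN_NEGATIVE,UNCERTAIN,STRONGLY_AGAINST
VERY_LOW_NULL,MARGINAL_NULL_UNCERTAIN_NEGATIVE,FAVORABLE,STRONGLY_AGAINST
VERY_LOW_NULL,MINOR,UNFAVORABLE,STRONGLY_AGAINST
VERY_LOW_NULL,MINOR,UNCERTAIN,STRONGLY_AGAINST
VERY_LOW_NULL,MINOR,FAVORABLE,MODERATELY_AGAINST
VERY_LOW_NULL,CONSIDERABLE,UNFAVORABLE,STRONGLY_AGAINST
VERY_LOW_NULL,CONSIDERABLE,UNCERTAIN,MODERATELY_AGAINST
VERY_LOW_NULL,CONSIDERABLE,FAVORABLE,UNCERTAIN
VERY_LOW_NULL,MAJOR,UNFAVORABLE,MODERATELY_AGAINST
VERY_LOW_NULL,MAJOR,UNCERTAIN,UNCERTAIN
VERY_LOW_NULL,MAJOR,FAVORABLE,MODERATELY_IN_FAVOR
LOW,MARGINAL_NULL_UNCERTAIN_NEGATIVE,UNFAVORABLE,STRONGLY_AGAINST
LOW,MARGINAL_NULL_UNCERTAIN_NEGATIVE,UNCERTAIN,STRONGLY_AGAINST
LOW,MARGINAL_NULL_UNCERTAIN_NEGATIVE,FAVORABLE,MODERATELY_AGAINST
LOW,MINOR,UNFAVORABLE,STRONGLY_AGAINST
LOW,MINOR,UNCERTAIN,STRONGLY_AGAINST
LOW,MINOR,FAVORABLE,UNCERTAIN
LOW,CONSIDERABLE,UNFAVORABLE,MODERATELY_AGAINST
LOW,CONSIDERABLE,UNCERTAIN,MODERATELY_AGAINST
LOW,CONSIDERABLE,FAVORABLE,MODERATELY_IN_FAVOR
LOW,MAJOR,UNFAVORABLE,UNCERTAIN
LOW,MAJOR,UNCERTAIN,UNCERTAIN
LOW,MAJOR,FAVORABLE,MODERATELY_IN_FAVOR
MODERATE,MARGINAL_NULL_UNCERTAIN_NEGATIVE,UNFAVORABLE,STRONGLY_AGAINST
MODERATE,MARGINAL_NULL_UNCERTAIN_NEGATIVE,UNCERTAIN,STRONGLY_AGAINST
MODERATE,MARGINAL_NULL_UNCERTAIN_NEGATIVE,FAVORABLE,MODERATELY_AGAINST
MODERATE,MINOR,UNFAVORABLE,STRONGLY_AGAINST
MODERATE,MINOR,UNCERTAIN,MODERATELY_AGAINST
MODERATE,MINOR,FAVORABLE,UNCERTAIN
MODERATE,CONSIDERABLE,UNFAVORABLE,MODERATELY_AGAINST
MODERATE,CONSIDERABLE,UNCERTAIN,UNCERTAIN
MODERATE,CONSIDERABLE,FAVORABLE,FULLY_IN_FAVOR
MODERATE,MAJOR,UNFAVORABLE,UNCERTAIN
MODERATE,MAJOR,UNCERTAIN,MODERATELY_IN_FAVOR
MODERATE,MAJOR,FAVORABLE,FULLY_IN_FAVOR
HIGH,MARGINAL_NULL_UNCERTAIN_NEGATIVE,UNFAVORABLE,STRONGLY_AGAINST
HIGH,MARGINAL_NULL_UNCERTAIN_NEGATIVE,UNCERTAIN,STRONGLY_AGAINST
HIGH,MARGINAL_NULL_UNCERTAIN_NEGATIVE,FAVORABLE,UNCERTAIN
HIGH,MINOR,UNFAVORABLE,MODERATELY_AGAINST
HIGH,MINOR,UNCERTAIN,MODERATELY_AGAINST
HIGH,MINOR,FAVORABLE,MODERATELY_IN_FAVOR
HIGH,CONSIDERABLE,UNFAVORABLE,UNCERTAIN
HIGH,CONSIDERABLE,UNCERTAIN,UNCERTAIN
HIGH,CONSIDERABLE,FAVORABLE,FULLY_IN_FAVOR
HIGH,MAJOR,UNFAVORABLE,MODERATELY_IN_FAVOR
HIGH,MAJOR,UNCERTAIN,MODERATELY_IN_FAVOR
HIGH,MAJOR,FAVORABLE,FULLY_IN_FAVOR
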