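<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic hand-written example of the EAF dialect understood by
     read_annotation_tier(): one fragmented instruction delivered in four
     utterance fragments (Utt-1..Utt-4) and one non-fragmented instruction,
     both by the instructor. Annotation values encode
     instruction:ordinal:referent. Times are in milliseconds. -->
<ANNOTATION_DOCUMENT AUTHOR="synthetic" DATE="2026-01-01T00:00:00+00:00"
    FORMAT="3.0" VERSION="3.0">
  <HEADER MEDIA_FILE="" TIME_UNITS="milliseconds"/>
  <TIME_ORDER>
    <TIME_SLOT TIME_SLOT_ID="ts1" TIME_VALUE="6000"/>
    <TIME_SLOT TIME_SLOT_ID="ts2" TIME_VALUE="8400"/>
    <TIME_SLOT TIME_SLOT_ID="ts3" TIME_VALUE="9200"/>
    <TIME_SLOT TIME_SLOT_ID="ts4" TIME_VALUE="10700"/>
    <TIME_SLOT TIME_SLOT_ID="ts5" TIME_VALUE="11500"/>
    <TIME_SLOT TIME_SLOT_ID="ts6" TIME_VALUE="12600"/>
    <TIME_SLOT TIME_SLOT_ID="ts7" TIME_VALUE="13400"/>
    <TIME_SLOT TIME_SLOT_ID="ts8" TIME_VALUE="14500"/>
    <TIME_SLOT TIME_SLOT_ID="ts9" TIME_VALUE="16000"/>
    <TIME_SLOT TIME_SLOT_ID="ts10" TIME_VALUE="20240"/>
  </TIME_ORDER>
  <TIER LINGUISTIC_TYPE_REF="instructions" PARTICIPANT="instructor"
      TIER_ID="instructor-utterances">
    <ANNOTATION>
      <ALIGNABLE_ANNOTATION ANNOTATION_ID="a1" TIME_SLOT_REF1="ts1"
          TIME_SLOT_REF2="ts2">
        <ANNOTATION_VALUE>i01:1:obj01</ANNOTATION_VALUE>
      </ALIGNABLE_ANNOTATION>
    </ANNOTATION>
    <ANNOTATION>
      <ALIGNABLE_ANNOTATION ANNOTATION_ID="a2" TIME_SLOT_REF1="ts3"
          TIME_SLOT_REF2="ts4">
        <ANNOTATION_VALUE>i01:2:obj01</ANNOTATION_VALUE>
      </ALIGNABLE_ANNOTATION>
    </ANNOTATION>
    <ANNOTATION>
      <ALIGNABLE_ANNOTATION ANNOTATION_ID="a3" TIME_SLOT_REF1="ts5"
          TIME_SLOT_REF2="ts6">
        <ANNOTATION_VALUE>i01:3:obj01</ANNOTATION_VALUE>
      </ALIGNABLE_ANNOTATION>
    </ANNOTATION>
    <ANNOTATION>
      <ALIGNABLE_ANNOTATION ANNOTATION_ID="a4" TIME_SLOT_REF1="ts7"
          TIME_SLOT_REF2="ts8">
        <ANNOTATION_VALUE>i01:4:obj01</ANNOTATION_VALUE>
      </ALIGNABLE_ANNOTATION>
    </ANNOTATION>
    <ANNOTATION>
      <ALIGNABLE_ANNOTATION ANNOTATION_ID="a5" TIME_SLOT_REF1="ts9"
          TIME_SLOT_REF2="ts10">
        <ANNOTATION_VALUE>i02:1:obj03</ANNOTATION_VALUE>
      </ALIGNABLE_ANNOTATION>
    </ANNOTATION>
  </TIER>
</ANNOTATION_DOCUMENT>
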