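hcw_id,patient_id,action_id,timestamp
A,1,FLOWSHEETS DATA SAVED,4/5/2020 2:14:25
A,1,CHART REVIEW ENCOUNTERS TAB SELECTED,4/5/2020 2:15:00
A,1,CHART REVIEW OTHER ORDERS TAB SELECTED,4/5/2020 2:18:23
A,1,HISTORY ACTIVITY ACCESSED,4/5/2020 2:19:53
A,1,FLOWSHEETS DATA COPIED FORWARD,4/5/2020 2:21:32
A,1,CHART REVIEW MEDICATIONS TAB SELECTED,4/5/2020 2:22:23
B,2,VISIT NAVIGATOR TEMPLATE LOADED,12/3/2020 6:31:27
B,2,SNAPSHOT REPORT VIEWED,12/3/2020 6:33:11
B,2,CHART REVIEW NOTES,12/3/2020 6:34:41
B,2,CHART REVIEW ENCOUNTER,12/3/2020 6:36:27
B,2,CHART REVIEW RESULTS,12/3/2020 6:37:33
B,2,CHART REVIEW OTHER ORDERS,12/3/2020 6:39:27
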